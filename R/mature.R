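#' Bundle the query material of one miRNA family
#'
#' @param family_id family name
#' @param alignment Stockholm alignment list (see [read_stockholm()]) with a
#'   consensus structure (`ss_cons`)
#' @param matures data.frame with columns `id`, `seq` (RNA, 15-30 nt) and
#'   `arm` ("5p", "3p" or "unknown"); miRBase-style `-5p`/`-3p` id suffixes
#'   are parsed into `arm` when that column is absent
#' @param cutoffs [family_cutoffs()] (optional until cm filtering is used)
#' @export
mirna_family <- function(family_id, alignment, matures, cutoffs = NULL) {
  if (is.null(matures$arm)) {
    matures$arm <- ifelse(grepl("-5p$", matures$id), "5p",
                   ifelse(grepl("-3p$", matures$id), "3p", "unknown"))
  }
  if (nrow(matures) < 1L) stop("family needs at least one mature sequence")
  matures$seq <- toupper(gsub("T", "U", matures$seq))
  len <- nchar(matures$seq)
  if (any(len < 15L | len > 30L))
    stop("mature sequence lengths must be in [15, 30] nt")
  structure(list(family_id = family_id, alignment = alignment,
                 matures = matures, cutoffs = cutoffs),
            class = "mirna_family")
}

#' Load a family bundle from a directory
#'
#' Expects `<dir>/<fam>.stk` (Stockholm with SS_cons) and
#' `<dir>/<fam>.mature.fa` (miRBase-dialect mature FASTA).
#' @param dir directory holding one family's files
#' @param family_id family name; default: directory basename
#' @param cutoffs optional [family_cutoffs()]
#' @export
read_family <- function(dir, family_id = basename(dir), cutoffs = NULL) {
  stk <- file.path(dir, paste0(family_id, ".stk"))
  mat <- file.path(dir, paste0(family_id, ".mature.fa"))
  if (!file.exists(stk)) stop("missing family alignment: ", stk)
  if (!file.exists(mat)) return(NULL)  # partial bundle; caller skips family
  seqs <- read_fasta(mat, as = "rna")
  mirna_family(family_id, read_stockholm(stk),
               data.frame(id = names(seqs), seq = unname(seqs),
                          stringsAsFactors = FALSE),
               cutoffs = cutoffs)
}

# Semi-global alignment of a short mature onto a precursor: global in the
# mature, free end gaps in the precursor. Linear gap model. Returns the
# best score, the leftmost best-scoring subject interval (0-based
# half-open) and the number of distinct co-optimal end positions.
semiglobal_align <- function(mature, precursor, match = 1, mismatch = -1,
                             gap = -2) {
  a <- strsplit(mature, "")[[1]]
  b <- strsplit(precursor, "")[[1]]
  m <- length(a); n <- length(b)
  jj <- seq_len(n)
  S <- matrix(0, nrow = m + 1L, ncol = n + 1L)
  S[, 1] <- gap * (0:m)
  for (i in seq_len(m)) {
    sub <- ifelse(b == a[i], match, mismatch)
    v <- pmax(S[i, jj] + sub, S[i, jj + 1L] + gap)
    # horizontal (subject-gap) moves: prefix-scan max(v[k] + gap*(j-k))
    lead <- c(S[i + 1L, 1L], v)
    best <- cummax(lead + gap * (0:n) * -1)  # max of lead[k]+|gap|*k
    S[i + 1L, jj + 1L] <- (best[jj + 1L] + gap * jj)
  }
  final <- S[m + 1L, -1L]
  score <- max(final)
  ends <- which(final == score)
  # traceback from the leftmost optimal end, preferring diagonal moves
  j <- ends[1L]; i <- m
  while (i > 0L) {
    sub <- if (j > 0L && b[j] == a[i]) match else mismatch
    if (j > 0L && S[i, j] + sub == S[i + 1L, j + 1L]) { i <- i - 1L; j <- j - 1L }
    else if (S[i, j + 1L] + gap == S[i + 1L, j + 1L]) i <- i - 1L
    else j <- j - 1L
  }
  list(score = score, start = j, end = ends[1L], n_optima = length(ends))
}

#' Place mature miR (and miR*) sequences on a candidate precursor
#'
#' Each family mature is aligned semi-globally (match +1, mismatch -1, gap
#' -2; global on the mature) against the precursor; the best-scoring
#' placement wins, provided it reaches the score floor of 0.6 x mature
#' length. Ties are resolved toward the 5' arm (leftmost placement) and
#' logged. If no annotated mature of the opposite arm aligns, the miR*
#' position is predicted as the window base-paired to the miR in the MFE
#' structure of the precursor.
#'
#' @param precursor precursor sequence (RNA or DNA), >= 40 nt
#' @param family [mirna_family()]
#' @param config see [default_config()]
#' @return a `mature_placement` (list with precursor_sequence,
#'   mir_interval, mirstar_interval (or NULL), mir_arm, alignment_score,
#'   source_mature_id), or NULL when no mature reaches the score floor
#'   ("no mature anchor"; the candidate is rejected downstream)
#' @export
locate_mature <- function(precursor, family, config = default_config()) {
  if (nchar(precursor) < 40L) stop("precursor shorter than 40 nt")
  prec <- toupper(gsub("T", "U", precursor))
  mats <- family$matures
  alns <- lapply(seq_len(nrow(mats)), function(i)
    semiglobal_align(mats$seq[i], prec, config$match, config$mismatch,
                     config$gap))
  scores <- vapply(alns, `[[`, 0, "score")
  floors <- config$mature_score_floor * nchar(mats$seq)
  ok <- scores >= floors
  if (!any(ok)) return(NULL)  # no mature anchor; rejected downstream
  best <- which(ok)[order(-scores[ok], vapply(alns[ok], `[[`, 0, "start"))][1]
  mir_aln <- alns[[best]]
  if (mir_aln$n_optima > 1L)
    message("mature '", mats$id[best], "' places equally at ",
            mir_aln$n_optima, " positions; keeping the 5'-most")
  mir <- c(mir_aln$start, mir_aln$end)
  # try an annotated mature for the opposite arm, disjoint from the miR
  star <- NULL; star_id <- NA_character_
  others <- setdiff(which(ok), best)
  others <- others[order(-scores[others])]
  for (i in others) {
    cand <- c(alns[[i]]$start, alns[[i]]$end)
    if (cand[1] >= mir[2] || cand[2] <= mir[1]) {
      star <- cand; star_id <- mats$id[i]; break
    }
  }
  if (is.null(star)) {
    fold <- fold_mfe(prec)
    p <- parse_dotbracket(fold$dotbracket)
    partners <- p[(mir[1] + 1L):mir[2]]
    partners <- partners[!is.na(partners)]
    if (length(partners) >= 0.5 * (mir[2] - mir[1])) {
      star <- c(min(partners) - 1L, max(partners))
      if (!(star[1] >= mir[2] || star[2] <= mir[1])) star <- NULL
    }
  }
  arm <- if (is.null(star)) {
    if ((mir[1] + mir[2]) / 2 <= nchar(prec) / 2) "5p" else "3p"
  } else if (mir[1] < star[1]) "5p" else "3p"
  structure(list(precursor_sequence = prec,
                 mir_interval = as.integer(mir),
                 mirstar_interval = if (is.null(star)) NULL else as.integer(star),
                 mir_arm = arm,
                 alignment_score = mir_aln$score,
                 source_mature_id = mats$id[best],
                 mirstar_source_id = star_id),
            class = "mature_placement")
}

#' Trim or extend a candidate interval around the mature placement
#'
#' The genomic interval is adjusted to span the miR and miR* plus `flank`
#' nt on each side, clipped to the chromosome. When the miR* could not be
#' placed, the span extends from the miR by 70 + flank nt toward the
#' predicted opposite arm. Idempotent once placements are stable.
#'
#' @param candidate_interval one-row interval data.frame (genome, 0-based)
#' @param placement [locate_mature()] result
#' @param flank nt added on each side (default 10)
#' @param chrom_length length of the target sequence, for clipping
#' @return adjusted one-row interval data.frame
#' @export
trim_precursor <- function(candidate_interval, placement, flank = 10L,
                           chrom_length = NULL) {
  iv <- candidate_interval
  to_genome <- function(local) {
    if (iv$strand == "+") c(iv$start + local[1], iv$start + local[2])
    else c(iv$end - local[2], iv$end - local[1])
  }
  g_mir <- to_genome(placement$mir_interval)
  if (!is.null(placement$mirstar_interval)) {
    g_star <- to_genome(placement$mirstar_interval)
    lo <- min(g_mir[1], g_star[1]) - flank
    hi <- max(g_mir[2], g_star[2]) + flank
  } else {
    ext <- 70L + flank
    towards_3p <- (placement$mir_arm == "5p")
    # 3' of the precursor is increasing genome coordinates on '+', the
    # reverse on '-'
    grow_hi <- (towards_3p && iv$strand == "+") ||
               (!towards_3p && iv$strand == "-")
    lo <- g_mir[1] - if (grow_hi) flank else ext
    hi <- g_mir[2] + if (grow_hi) ext else flank
  }
  lo <- max(0L, as.integer(lo))
  if (!is.null(chrom_length)) hi <- min(as.integer(chrom_length), as.integer(hi))
  genomic_interval(iv$seqid, lo, as.integer(hi), iv$strand)
}

#' Check mature placement against the precursor fold
#'
#' A canonical precursor folds into a single stem-loop with the miR and
#' miR* on opposite arms. The verdict is `valid` iff (i) exactly one
#' hairpin loop lies within the miR..miR* span, (ii) neither mature
#' overlaps that loop by more than the tolerance (default 3 nt; processing
#' is not nucleotide-exact), and (iii) the two matures flank the loop on
#' opposite sides. Multiple loops in the span give `multiloop`; matures on
#' one side give `same_arm`; excessive loop overlap gives `loop_overlap`.
#'
#' @param placement [locate_mature()] result
#' @param fold [fold_mfe()] result for the placed precursor
#' @param config see [default_config()]
#' @return one of "valid", "loop_overlap", "multiloop", "same_arm"
#' @export
check_arm_consistency <- function(placement, fold, config = default_config()) {
  tol <- config$loop_overlap_tolerance
  loops <- hairpin_loops(fold$dotbracket)
  mir <- placement$mir_interval
  star <- placement$mirstar_interval
  span <- if (is.null(star)) c(0L, nchar(fold$dotbracket))
          else c(min(mir[1], star[1]), max(mir[2], star[2]))
  inside <- loops[intervals_overlap(loops$start, loops$end, span[1], span[2]), ,
                  drop = FALSE]
  if (nrow(inside) > 1L) return("multiloop")
  if (nrow(inside) == 0L) return("same_arm")
  loop <- inside[1, ]
  ov <- function(x) {
    if (is.null(x)) return(0L)
    max(0L, min(x[2], loop$end) - max(x[1], loop$start))
  }
  if (ov(mir) > tol || ov(star) > tol) return("loop_overlap")
  if (!is.null(star)) {
    side <- function(x) if (x[2] <= loop$start + tol) -1L
                        else if (x[1] >= loop$end - tol) 1L else 0L
    if (side(mir) == 0L || side(star) == 0L || side(mir) == side(star))
      return("same_arm")
  }
  "valid"
}
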