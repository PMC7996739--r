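can_pair <- function(x, y) {
  paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# Thread a candidate sequence into the column space of a family alignment,
# anchored on the first alignment row (semi-global: the row is global, the
# candidate local, so flanking candidate sequence is trimmed and candidate
# insertions relative to the row are dropped).
thread_candidate <- function(alignment, candidate) {
  rows <- alignment$rows
  if (length(rows) == 0L) stop("empty family alignment")
  template_gapped <- rows[[1]]
  template <- gsub("-", "", template_gapped, fixed = TRUE)
  cand <- toupper(gsub("T", "U", candidate))
  # exact-duplicate fast path: candidate identical to a degapped row
  for (r in rows) {
    if (gsub("-", "", r, fixed = TRUE) == cand) return(r)
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::RNAString(template),
    subject = Biostrings::RNAString(cand),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE, type = "RNA"),
    gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  # map template position -> candidate character
  mapped <- rep("-", nchar(template))
  ti <- 0L
  for (k in seq_along(pa)) {
    if (pa[k] != "-") {
      ti <- ti + 1L
      if (sa[k] != "-") mapped[ti] <- sa[k]
    }
  }
  # expand into alignment columns along the gapped template row
  cols <- strsplit(template_gapped, "")[[1]]
  out <- character(length(cols))
  ti <- 0L
  for (k in seq_along(cols)) {
    if (cols[k] == "-") out[k] <- "-"
    else { ti <- ti + 1L; out[k] <- mapped[ti] }
  }
  paste(out, collapse = "")
}

# Consensus structure of an alignment restricted to the anchor pairs of
# SS_cons: a pair is kept iff a strict majority of the distinct rows can
# form a Watson-Crick or GU wobble pair at its two columns.
majority_consensus <- function(rows, ss_cons) {
  p <- parse_dotbracket(ss_cons)
  n <- nchar(ss_cons)
  rows <- unique(toupper(gsub("T", "U", rows)))
  chars <- strsplit(rows, "")
  out <- rep(".", n)
  for (i in seq_len(n)) {
    j <- p[i]
    if (is.na(j) || j <= i) next
    support <- sum(vapply(chars, function(r) can_pair(r[i], r[j]), NA))
    if (support > length(rows) / 2) { out[i] <- "("; out[j] <- ")" }
  }
  paste(out, collapse = "")
}

# RNAalifold-compatible adapter: consensus of an alignment via the
# alignment folder on PATH.
alifold_consensus <- function(rows, engine = "RNAalifold") {
  if (!nzchar(Sys.which(engine)))
    stop("alignment folding engine '", engine, "' not found on PATH")
  tmp <- tempfile(fileext = ".stk")
  on.exit(unlink(tmp))
  write_stockholm(list(family_id = "aln", rows = rows, ss_cons = ""), tmp)
  out <- system2(engine, c("--noPS", "-f", "S", tmp), stdout = TRUE)
  line <- grep("^[().,]+\\s+\\(", out, value = TRUE)
  if (!length(line)) stop("could not parse alignment folder output")
  normalize_ss(sub("\\s.*$", "", line[1]))
}

#' Family consensus structure with and without a candidate
#'
#' The candidate is threaded into the family alignment (anchored on the
#' alignment itself; gaps opened as needed, candidate insertions dropped)
#' and the consensus structure is recomputed over the augmented alignment.
#' Both the default and the augmented consensus are returned in a common
#' coordinate system (columns that are gap-only in the augmented alignment
#' are removed from both), ready for the tree edit distance.
#'
#' With the default `consensus_method = "majority"`, a SS_cons anchor pair
#' survives iff a strict majority of the distinct rows can form a WC/GU
#' pair at its columns; duplicate rows carry no extra weight, so adding an
#' exact copy of a member never changes the consensus. Method "alifold"
#' instead delegates both consensus computations to an
#' RNAalifold-compatible engine.
#'
#' @param family [mirna_family()] with a non-empty structure-annotated
#'   alignment
#' @param candidate_sequence precursor sequence of the candidate
#' @param config see [default_config()]
#' @return list with `css_default`, `css_with_candidate` (dot-bracket
#'   strings of equal length) and `candidate_row` (the threaded row)
#' @export
consensus_with_candidate <- function(family, candidate_sequence,
                                     config = default_config()) {
  aln <- family$alignment
  if (length(aln$rows) == 0L) stop("empty family alignment")
  if (!nzchar(aln$ss_cons)) stop("family alignment lacks SS_cons")
  cand_row <- thread_candidate(aln, candidate_sequence)
  rows_aug <- c(aln$rows, candidate = cand_row)
  if (config$consensus_method == "alifold") {
    css_default <- alifold_consensus(aln$rows)
    css_with <- alifold_consensus(rows_aug)
  } else {
    css_default <- majority_consensus(aln$rows, aln$ss_cons)
    css_with <- majority_consensus(rows_aug, aln$ss_cons)
  }
  # common coordinates: drop columns gapped in every augmented row
  chars <- strsplit(rows_aug, "")
  keep <- Reduce(`|`, lapply(chars, function(r) r != "-"))
  css_default <- mask_columns(css_default, keep)
  css_with <- mask_columns(css_with, keep)
  list(css_default = css_default, css_with_candidate = css_with,
       candidate_row = cand_row)
}

# Remove masked columns from a dot-bracket, dropping any pair with an
# endpoint in a removed column so the result stays balanced.
mask_columns <- function(dotbracket, keep) {
  p <- parse_dotbracket(dotbracket)
  ch <- strsplit(dotbracket, "")[[1]]
  drop_pair <- !is.na(p) & (!keep | !keep[p])
  ch[drop_pair] <- "."
  paste(ch[keep], collapse = "")
}

#' Run the structural filter cascade on one candidate
#'
#' Applies, in order: precursor length <= 200 nt; mature placement present
#' ("no mature anchor" otherwise); fold MFE <= -10 kcal/mol; arm
#' consistency of the placement against the fold. Candidates passing all
#' four are accepted and assigned a confidence: High iff the augmented
#' family consensus is still valid (>= 1 hairpin and >= 50% of the default
#' consensus pairs retained) and the tree edit distance between the
#' default and augmented consensus is <= 7; Medium otherwise.
#'
#' @param candidate_sequence trimmed precursor sequence
#' @param placement [locate_mature()] result, or NULL if placement failed
#' @param family [mirna_family()]
#' @param config see [default_config()]
#' @return an `evaluation_result` list: length_ok, mfe_ok, mfe,
#'   arm_verdict, ted, css_valid, confidence, final_status, reject_reason
#' @export
evaluate_candidate <- function(candidate_sequence, placement, family,
                               config = default_config()) {
  res <- list(length_ok = NA, mfe_ok = NA, mfe = NA_real_,
              arm_verdict = NA_character_, ted = NA_integer_,
              css_valid = NA, confidence = NA_character_,
              final_status = "discarded", reject_reason = NA_character_)
  class(res) <- "evaluation_result"
  res$length_ok <- nchar(candidate_sequence) <= config$max_precursor_length
  if (!res$length_ok) { res$reject_reason <- "length"; return(res) }
  if (is.null(placement)) { res$reject_reason <- "no mature anchor"; return(res) }
  fold <- fold_mfe(candidate_sequence)
  res$mfe <- fold$mfe
  res$mfe_ok <- if (config$mfe_inclusive) fold$mfe <= config$mfe_threshold
                else fold$mfe < config$mfe_threshold
  if (!res$mfe_ok) { res$reject_reason <- "mfe"; return(res) }
  res$arm_verdict <- check_arm_consistency(placement, fold, config)
  if (res$arm_verdict != "valid") {
    res$reject_reason <- res$arm_verdict
    return(res)
  }
  css <- consensus_with_candidate(family, candidate_sequence, config)
  res$ted <- tree_edit_distance(css$css_default, css$css_with_candidate)
  open_default <- strsplit(css$css_default, "")[[1]] == "("
  open_with <- strsplit(css$css_with_candidate, "")[[1]] == "("
  retention <- if (!any(open_default)) 1
               else sum(open_default & open_with) / sum(open_default)
  res$css_valid <- nrow(hairpin_loops(css$css_with_candidate)) >= 1L &&
    retention >= config$min_pair_retention
  res$final_status <- "accepted"
  res$confidence <- if (res$css_valid && res$ted <= config$ted_threshold)
    "High" else "Medium"
  res
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("evaluation_result:", x$final_status,
      if (!is.na(x$confidence)) paste0("(", x$confidence, ")")
      else paste0("[", x$reject_reason, "]"),
      "\n  mfe =", x$mfe, " arm =", x$arm_verdict, " ted =", x$ted, "\n")
  invisible(x)
}
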