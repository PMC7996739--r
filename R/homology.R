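#' Default pipeline configuration
#'
#' Thresholds of the filter cascade, overridable per run or via a YAML
#' config. Values: blast/cm hits must reach E-value <= 0.01 and coverage
#' >= 70%; blast HSPs must span >= 20 nt; cm hits additionally need
#' bitscore > log2(2N) for genome size N, or are rescued when
#' bitscore / gathering-cutoff >= 0.32; per-family candidate lists are
#' capped at the 100 best bitscores; precursors must be <= 200 nt with
#' fold MFE <= -10 kcal/mol; High confidence needs a valid consensus
#' structure and tree edit distance <= 7.
#'
#' @param ... overrides of individual entries
#' @return named list of configuration values
#' @export
default_config <- function(...) {
  cfg <- list(
    evalue = 0.01,
    coverage = 0.70,
    min_hsp = 20L,
    nbit_factor = 0.32,
    candidate_cap = 100L,
    max_precursor_length = 200L,
    mfe_threshold = -10.0,
    mfe_inclusive = TRUE,
    ted_threshold = 7L,
    flank = 10L,
    mature_score_floor = 0.6,
    match = 1, mismatch = -1, gap = -2,
    loop_overlap_tolerance = 3L,
    min_pair_retention = 0.5,
    consensus_method = "majority",
    genome_size = NULL)
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

#' Read a YAML configuration, filling unspecified keys with defaults
#' @param path YAML file with any subset of the [default_config()] keys
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Family-level score cutoffs
#'
#' @param gathering_cutoff Rfam-style family gathering cutoff (bits), or NULL
#' @param genome_size target genome size N in nt (drives the log2(2N)
#'   bitscore cutoff for covariance-model hits)
#' @export
family_cutoffs <- function(gathering_cutoff = NULL, genome_size) {
  if (!is.null(gathering_cutoff) && gathering_cutoff <= 0)
    stop("gathering cutoff must be positive")
  if (genome_size <= 0) stop("genome size must be positive")
  list(gathering_cutoff = gathering_cutoff, genome_size = genome_size)
}

#' Sequence-homology filter for pairwise (blastn) hits
#'
#' Keeps hits with E-value <= 0.01, HSP length >= 20 nt and coverage >= 70%
#' (all boundaries inclusive; thresholds from the configuration).
#'
#' @param hits hit data.frame from [read_tabular_hits()]
#' @param config see [default_config()]
#' @return the accepted subset, same columns
#' @export
filter_sequence_hits <- function(hits, config = default_config()) {
  if (nrow(hits) == 0L) return(hits)
  keep <- hits$evalue <= config$evalue &
    hits$hsp_length >= config$min_hsp &
    !is.na(hits$coverage) & hits$coverage >= config$coverage
  hits[keep, , drop = FALSE]
}

#' Filter for nhmmer hits
#'
#' nhmmer applies its own model-specific inclusion thresholds; on top of
#' those only E-value <= 0.01 is required (no coverage test).
#' @inheritParams filter_sequence_hits
#' @export
filter_hmm_hits <- function(hits, config = default_config()) {
  if (nrow(hits) == 0L) return(hits)
  hits[hits$evalue <= config$evalue, , drop = FALSE]
}

#' Alignment-score filter for covariance-model (cmsearch) hits
#'
#' A hit is kept iff E-value <= 0.01, coverage >= 70%, and its bitscore
#' clears the uniform genome-size cutoff `log2(2 N)` -- or, when the family
#' has a gathering cutoff ge, it is rescued by the normalized bitscore rule
#' `nBit = bitscore / ge >= 0.32`.
#'
#' @inheritParams filter_sequence_hits
#' @param cutoffs [family_cutoffs()] with the genome size and optional
#'   gathering cutoff
#' @export
filter_cm_hits <- function(hits, cutoffs, config = default_config()) {
  if (nrow(hits) == 0L) return(hits)
  if (!is.null(cutoffs$gathering_cutoff) && cutoffs$gathering_cutoff <= 0)
    stop("gathering cutoff must be positive")
  uniform <- hits$bitscore > log2(2 * cutoffs$genome_size)
  rescued <- if (is.null(cutoffs$gathering_cutoff)) rep(FALSE, nrow(hits))
             else hits$bitscore / cutoffs$gathering_cutoff >= config$nbit_factor
  keep <- hits$evalue <= config$evalue &
    !is.na(hits$coverage) & hits$coverage >= config$coverage &
    (uniform | rescued)
  hits[keep, , drop = FALSE]
}

new_region <- function(iv, family_id, hits, status = "candidate") {
  r <- iv
  r$family_id <- family_id
  r$best_bitscore <- max(hits$bitscore)
  r$best_evalue <- min(hits$evalue)
  r$best_coverage <- if (all(is.na(hits$coverage))) NA_real_
                     else max(hits$coverage, na.rm = TRUE)
  r$status <- status
  r$hits <- I(list(hits))
  r
}

empty_regions <- function() {
  r <- data.frame(seqid = character(0), start = integer(0), end = integer(0),
                  strand = character(0), family_id = character(0),
                  best_bitscore = numeric(0), best_evalue = numeric(0),
                  best_coverage = numeric(0), status = character(0),
                  stringsAsFactors = FALSE)
  r$hits <- I(list())
  r
}

#' Aggregate overlapping hits into extended candidate regions
#'
#' Hits on the same sequence and strand whose half-open intervals share at
#' least one nucleotide (after transitive closure) form one region spanning
#' their union; abutting intervals do not merge. The result is sorted by
#' (seqid, start, strand) and is independent of input order. Strands are
#' kept separate at this step.
#'
#' @param hits hit data.frame sharing one family id
#' @return region data.frame: interval columns, family_id, best_bitscore,
#'   best_evalue, best_coverage, status, and a `hits` list column of the
#'   supporting hits
#' @export
merge_hits_to_regions <- function(hits) {
  if (nrow(hits) == 0L) return(empty_regions())
  fam <- unique(hits$family_id)
  if (length(fam) != 1L) stop("hits must share a single family_id")
  out <- list()
  for (key in sort(unique(paste(hits$seqid, hits$strand)))) {
    sub <- hits[paste(hits$seqid, hits$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    grp <- integer(nrow(sub)); g <- 1L; grp[1] <- 1L
    hi <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] < hi) {          # strict overlap, half-open
        grp[i] <- g; hi <- max(hi, sub$end[i])
      } else {
        g <- g + 1L; grp[i] <- g; hi <- sub$end[i]
      }
    }
    for (gi in seq_len(g)) {
      h <- sub[grp == gi, , drop = FALSE]
      iv <- genomic_interval(h$seqid[1], min(h$start), max(h$end), h$strand[1])
      out[[length(out) + 1L]] <- new_region(iv, fam, h)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seqid, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Resolve overlapping candidate regions on opposite strands
#'
#' When the same family produces overlapping candidates on both strands,
#' the engines' quality measures decide the reading direction: higher best
#' bitscore, then lower best E-value, then higher best coverage. The loser
#' is retained with `status = "rejected_strand"` for the report. An exact
#' tie on all three keeps the plus strand and emits a warning.
#'
#' @param regions region data.frame for one family (both strands)
#' @return the same regions with status updated on strand-rejected rows
#' @export
disambiguate_strands <- function(regions) {
  if (nrow(regions) < 2L) return(regions)
  plus <- which(regions$strand == "+" & regions$status == "candidate")
  minus <- which(regions$strand == "-" & regions$status == "candidate")
  for (i in plus) for (j in minus) {
    if (regions$status[i] != "candidate" || regions$status[j] != "candidate")
      next
    if (regions$seqid[i] != regions$seqid[j]) next
    if (!intervals_overlap(regions$start[i], regions$end[i],
                           regions$start[j], regions$end[j])) next
    cmp <- compare_quality(regions[i, ], regions[j, ])
    if (cmp == 0L) {
      warning("exact quality tie between strands at ",
              format_locus(regions[i, ]), "; keeping '+'")
      loser <- j
    } else loser <- if (cmp > 0L) j else i
    regions$status[loser] <- "rejected_strand"
  }
  regions
}

# >0 if a beats b, <0 if b beats a, 0 tie
compare_quality <- function(a, b) {
  if (a$best_bitscore != b$best_bitscore)
    return(sign(a$best_bitscore - b$best_bitscore))
  if (a$best_evalue != b$best_evalue)
    return(sign(b$best_evalue - a$best_evalue))
  ca <- ifelse(is.na(a$best_coverage), -Inf, a$best_coverage)
  cb <- ifelse(is.na(b$best_coverage), -Inf, b$best_coverage)
  sign(ca - cb)
}

#' Merge candidate regions found by different search engines
#'
#' Same-family regions overlapping on the same strand are unified: the
#' interval becomes the union, supporting hits are concatenated, and the
#' best scores are the max bitscore / min E-value / max coverage over the
#' merged set. Regions found by only one engine are retained unchanged.
#'
#' @param ... region data.frames (e.g. blast, hmm, cm), all strand-resolved
#' @return merged region data.frame
#' @export
merge_engines <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0L, list(...))
  if (length(parts) == 0L) return(empty_regions())
  all <- do.call(rbind, parts)
  live <- all[all$status == "candidate", , drop = FALSE]
  rest <- all[all$status != "candidate", , drop = FALSE]
  if (nrow(live) == 0L) return(all)
  out <- list()
  for (key in sort(unique(paste(live$family_id, live$seqid, live$strand)))) {
    sub <- live[paste(live$family_id, live$seqid, live$strand) == key, ,
                drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    grp <- integer(nrow(sub)); g <- 1L; grp[1] <- 1L
    hi <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] < hi) { grp[i] <- g; hi <- max(hi, sub$end[i]) }
      else { g <- g + 1L; grp[i] <- g; hi <- sub$end[i] }
    }
    for (gi in seq_len(g)) {
      r <- sub[grp == gi, , drop = FALSE]
      iv <- genomic_interval(r$seqid[1], min(r$start), max(r$end), r$strand[1])
      hits <- do.call(rbind, r$hits)
      out[[length(out) + 1L]] <- new_region(iv, r$family_id[1], hits)
    }
  }
  res <- do.call(rbind, c(out, if (nrow(rest)) list(rest)))
  res <- res[order(res$family_id, res$seqid, res$start, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cap a family's candidate list at the best bitscores
#'
#' Only the `limit` candidates with the best bitscores proceed to mature
#' annotation; the remainder are flagged `potential` and reported for later
#' manual inspection. Ties at the boundary are broken by lower E-value,
#' then genomic order (seqid, start, strand), so the outcome is
#' deterministic.
#'
#' @param regions strand-resolved region data.frame for one family
#' @param limit maximum number of candidates processed further (default 100)
#' @return list with elements `processed` and `potential`
#' @export
cap_candidates <- function(regions, limit = 100L) {
  live <- regions[regions$status == "candidate", , drop = FALSE]
  rest <- regions[regions$status != "candidate", , drop = FALSE]
  if (nrow(live) <= limit)
    return(list(processed = regions, potential = empty_regions()))
  ord <- order(-live$best_bitscore, live$best_evalue,
               live$seqid, live$start, live$strand)
  live <- live[ord, , drop = FALSE]
  idx <- seq_len(min(limit, nrow(live)))
  potential <- live[setdiff(seq_len(nrow(live)), idx), , drop = FALSE]
  potential$status <- rep("potential", nrow(potential))
  processed <- live[idx, , drop = FALSE]
  processed <- rbind(processed, rest)
  processed <- processed[order(processed$seqid, processed$start), , drop = FALSE]
  rownames(processed) <- NULL; rownames(potential) <- NULL
  list(processed = processed, potential = potential)
}
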