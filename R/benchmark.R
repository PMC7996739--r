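#' Classify candidate and reference loci (Match / Miss / Additional)
#'
#' A reference locus is a *Match* when at least one candidate overlaps it
#' by >= 1 nt on the same strand (optionally a minimum overlap fraction of
#' the reference locus), otherwise a *Miss*. A candidate overlapping no
#' same-strand reference locus is *Additional*. Record order in either
#' input is irrelevant.
#'
#' @param candidates,reference interval data.frames (internal 0-based
#'   half-open; see [read_annotation()])
#' @param min_fraction minimum overlap as a fraction of the reference
#'   locus (default 0: any shared nucleotide)
#' @return list with `reference` (input plus `class` Match/Miss),
#'   `candidates` (input plus `class` Match/Additional) and `summary` (a
#'   one-row data.frame: n_annotation, n_match, n_miss, ratio_match,
#'   ratio_miss, n_additional)
#' @export
classify_loci <- function(candidates, reference, min_fraction = 0) {
  n_ann <- nrow(reference)
  if (n_ann == 0L) {
    cand_class <- rep("Additional", nrow(candidates))
    summary <- data.frame(n_annotation = 0L, n_match = 0L, n_miss = 0L,
                          ratio_match = NA_real_, ratio_miss = NA_real_,
                          n_additional = nrow(candidates))
    reference$class <- character(0)
    candidates$class <- cand_class
    return(list(reference = reference, candidates = candidates,
                summary = summary))
  }
  ref_matched <- rep(FALSE, n_ann)
  cand_matched <- rep(FALSE, nrow(candidates))
  if (nrow(candidates) > 0L) {
    ov <- GenomicRanges::findOverlaps(as_granges0(candidates),
                                      as_granges0(reference),
                                      ignore.strand = FALSE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    if (min_fraction > 0 && length(qh)) {
      w <- pmin(candidates$end[qh], reference$end[sh]) -
           pmax(candidates$start[qh], reference$start[sh])
      frac <- w / (reference$end[sh] - reference$start[sh])
      keep <- frac >= min_fraction
      qh <- qh[keep]; sh <- sh[keep]
    }
    ref_matched[unique(sh)] <- TRUE
    cand_matched[unique(qh)] <- TRUE
  }
  reference$class <- ifelse(ref_matched, "Match", "Miss")
  candidates$class <- ifelse(cand_matched, "Match", "Additional")
  n_match <- sum(ref_matched)
  summary <- data.frame(
    n_annotation = n_ann, n_match = n_match, n_miss = n_ann - n_match,
    ratio_match = n_match / n_ann, ratio_miss = (n_ann - n_match) / n_ann,
    n_additional = sum(!cand_matched))
  list(reference = reference, candidates = candidates, summary = summary)
}

#' Per-family overlap class (Perfect / Partial / Without)
#'
#' @param n_matched,n_annotated matched and total annotated loci of a family
#' @return "Perfect" if every annotated locus is matched, "Partial" if some
#'   are, "Without" if none is
#' @export
classify_family_overlap <- function(n_matched, n_annotated) {
  stopifnot(n_annotated >= 1L, n_matched <= n_annotated)
  ifelse(n_matched == n_annotated, "Perfect",
         ifelse(n_matched > 0L, "Partial", "Without"))
}

#' Categorize Additional candidates against an auxiliary annotation
#'
#' Each Additional candidate is assigned the highest-priority overlapping
#' feature category under the strict hierarchy different-miRNA > repeat >
#' other (non-intergenic); candidates overlapping nothing are intergenic.
#' The auxiliary annotation must carry a `category` column with values in
#' {"miRNA", "repeat", "other"} (a GFF3 `type` column is mapped: miRNA-ish
#' types to "miRNA", repeat-ish to "repeat", the rest to "other").
#'
#' @param candidates Additional-candidate interval data.frame
#' @param aux auxiliary annotation data.frame, or NULL (everything left
#'   uncategorized)
#' @param ignore_strand compare irrespective of strand (default FALSE)
#' @return character vector: "different-miRNA", "repeat", "other",
#'   "intergenic", or NA when no auxiliary annotation was supplied
#' @export
annotate_additional <- function(candidates, aux, ignore_strand = FALSE) {
  if (is.null(aux)) return(rep(NA_character_, nrow(candidates)))
  if (is.null(aux$category)) {
    type <- if (!is.null(aux$type)) aux$type else rep("other", nrow(aux))
    aux$category <- ifelse(grepl("miRNA", type, ignore.case = TRUE), "miRNA",
                    ifelse(grepl("repeat|transposon", type,
                                 ignore.case = TRUE), "repeat", "other"))
  }
  out <- rep("intergenic", nrow(candidates))
  if (nrow(candidates) == 0L || nrow(aux) == 0L) return(out)
  ov <- GenomicRanges::findOverlaps(as_granges0(candidates), as_granges0(aux),
                                    ignore.strand = ignore_strand)
  rank <- c("miRNA" = 1L, "repeat" = 2L, "other" = 3L)
  lab <- c("different-miRNA", "repeat", "other")
  for (i in unique(S4Vectors::queryHits(ov))) {
    cats <- aux$category[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]
    out[i] <- lab[min(rank[cats])]
  }
  out
}

#' Summary table in the benchmark column layout
#'
#' One row per family: counts through the pipeline stages plus the
#' Match/Miss classification against the reference.
#' @param per_family list of per-family stats (see [run_annotate()])
#' @return data.frame with columns Family, Homology, Final, Filtered, Ann.,
#'   Match, Miss, Ratio_Match, Ratio_Miss, Add., High, Medium
#' @export
summary_table <- function(per_family) {
  do.call(rbind, lapply(per_family, as.data.frame))
}
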