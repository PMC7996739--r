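#' Genomic interval plumbing
#'
#' All coordinates inside the package are 0-based, half-open `[start, end)`,
#' with an explicit strand (`+` or `-`); conversion to the 1-based inclusive
#' convention of GFF3 and the tabular search-engine outputs happens only at
#' I/O boundaries. Intervals are rows of ordinary data frames with columns
#' `seqid`, `start`, `end`, `strand`.
#'
#' @param seqid character vector of sequence (chromosome) names
#' @param start,end integer vectors, 0-based half-open
#' @param strand character vector of "+" or "-"
#' @return a data.frame with one row per interval
#' @export
genomic_interval <- function(seqid, start, end, strand) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be integral")
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval must satisfy start < end")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be explicit '+' or '-'")
  data.frame(seqid = as.character(seqid), start = start, end = end,
             strand = as.character(strand), stringsAsFactors = FALSE)
}

#' Do two half-open intervals on the same sequence share at least one base?
#' @keywords internal
intervals_overlap <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}

#' Convert an internal interval data.frame to a GRanges (1-based inclusive)
#' @keywords internal
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
}
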