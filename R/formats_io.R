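#' Read a FASTA file into a named character vector
#'
#' Sequence identifiers are the first whitespace-delimited token of the
#' header. The alphabet is restricted to `A,C,G,T,U,N` (case-insensitive);
#' by default U is normalized to T (genomic/DNA context), with `as = "rna"`
#' T is normalized to U instead.
#'
#' @param path FASTA file
#' @param as "dna" (default; U -> T) or "rna" (T -> U)
#' @return named character vector of upper-case sequences (possibly empty)
#' @export
read_fasta <- function(path, as = c("dna", "rna")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(setNames(character(0), character(0)))
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA record (sequence before header) at line ", first)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- vapply(names(set), function(h) strsplit(h, "\\s+")[[1]][1], "")
  bad <- grepl("[^ACGTUN]", seqs)
  if (any(bad))
    stop("sequence '", ids[which(bad)[1]], "' contains characters outside {A,C,G,T,U,N}")
  seqs <- if (as == "dna") gsub("U", "T", seqs, fixed = TRUE)
          else gsub("T", "U", seqs, fixed = TRUE)
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#' @param seqs named character vector
#' @param path output file
#' @param width line width
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

engine_of_dialect <- c("blast-tab6" = "blast",
                       "nhmmer-tblout" = "hmm",
                       "cmsearch-tblout" = "cm")

#' Parse tabular homology-search output into a hit table
#'
#' Supports NCBI BLAST `-outfmt 6`, `nhmmer --tblout` and
#' `cmsearch --tblout`. Engines report 1-based inclusive coordinates and
#' encode the minus strand as `from > to`; both are normalized here, so the
#' returned table always satisfies `start < end` in 0-based half-open
#' coordinates with an explicit strand. Comment lines (`#`) are skipped.
#'
#' Coverage is the aligned fraction of the query: aligned query length over
#' query sequence length for blast (requires `query_lengths`), aligned model
#' length over model length for nhmmer/cmsearch (requires `model_lengths`);
#' `NA` when the denominator is unknown.
#'
#' @param path tabular output file
#' @param dialect one of "blast-tab6", "nhmmer-tblout", "cmsearch-tblout"
#' @param query_lengths named numeric: query sequence lengths (blast)
#' @param model_lengths named numeric: HMM/CM model lengths (nhmmer/cmsearch)
#' @param query_family optional named character mapping query/model name to a
#'   family id; defaults to using the query name itself
#' @return data.frame with columns seqid, start, end, strand, family_id,
#'   engine, evalue, bitscore, hsp_length, coverage
#' @export
read_tabular_hits <- function(path, dialect,
                              query_lengths = NULL, model_lengths = NULL,
                              query_family = NULL) {
  if (!dialect %in% names(engine_of_dialect))
    stop("unknown dialect: ", dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(keep) == 0L) return(empty_hits())
  num <- function(x, field, lineno) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v)))
      stop("non-numeric ", field, " field at line ", lineno[which(is.na(v))[1]])
    v
  }
  fam <- function(q) {
    if (is.null(query_family)) q
    else ifelse(q %in% names(query_family), unname(query_family[q]), q)
  }
  tok <- strsplit(trimws(lines[keep]), "\\s+")
  if (dialect == "blast-tab6") {
    if (any(lengths(tok) < 12L))
      stop("blast-tab6 line with fewer than 12 fields at line ",
           keep[which(lengths(tok) < 12L)[1]])
    m <- do.call(rbind, lapply(tok, `[`, 1:12))
    qid <- m[, 1]; sid <- m[, 2]
    alen  <- num(m[, 4], "length", keep)
    qfrom <- num(m[, 7], "qstart", keep); qto <- num(m[, 8], "qend", keep)
    sfrom <- num(m[, 9], "sstart", keep); sto <- num(m[, 10], "send", keep)
    ev    <- num(m[, 11], "evalue", keep); bit <- num(m[, 12], "bitscore", keep)
    cov <- if (is.null(query_lengths)) rep(NA_real_, length(qid))
           else (abs(qto - qfrom) + 1) / as.numeric(query_lengths[qid])
    hits_from_engine(sid, sfrom, sto, fam(qid), "blast", ev, bit, alen, cov)
  } else if (dialect == "nhmmer-tblout") {
    if (any(lengths(tok) < 14L))
      stop("nhmmer tblout line with fewer than 14 fields at line ",
           keep[which(lengths(tok) < 14L)[1]])
    m <- do.call(rbind, lapply(tok, `[`, 1:14))
    sid <- m[, 1]; qid <- m[, 3]
    hfrom <- num(m[, 5], "hmmfrom", keep); hto <- num(m[, 6], "hmm to", keep)
    afrom <- num(m[, 7], "alifrom", keep); ato <- num(m[, 8], "ali to", keep)
    ev  <- num(m[, 13], "E-value", keep); bit <- num(m[, 14], "score", keep)
    cov <- if (is.null(model_lengths)) rep(NA_real_, length(qid))
           else (abs(hto - hfrom) + 1) / as.numeric(model_lengths[qid])
    hits_from_engine(sid, afrom, ato, fam(qid), "hmm", ev, bit,
                     abs(ato - afrom) + 1, cov)
  } else {
    if (any(lengths(tok) < 17L))
      stop("cmsearch tblout line with fewer than 17 fields at line ",
           keep[which(lengths(tok) < 17L)[1]])
    m <- do.call(rbind, lapply(tok, `[`, 1:17))
    sid <- m[, 1]; qid <- m[, 3]
    mfrom <- num(m[, 6], "mdl from", keep); mto <- num(m[, 7], "mdl to", keep)
    sfrom <- num(m[, 8], "seq from", keep); sto <- num(m[, 9], "seq to", keep)
    bit <- num(m[, 15], "score", keep); ev <- num(m[, 16], "E-value", keep)
    cov <- if (is.null(model_lengths)) rep(NA_real_, length(qid))
           else (abs(mto - mfrom) + 1) / as.numeric(model_lengths[qid])
    hits_from_engine(sid, sfrom, sto, fam(qid), "cm", ev, bit,
                     abs(sto - sfrom) + 1, cov)
  }
}

empty_hits <- function() {
  data.frame(seqid = character(0), start = integer(0), end = integer(0),
             strand = character(0), family_id = character(0),
             engine = character(0), evalue = numeric(0), bitscore = numeric(0),
             hsp_length = integer(0), coverage = numeric(0),
             stringsAsFactors = FALSE)
}

# 1-based inclusive engine coordinates -> internal; from > to means minus.
hits_from_engine <- function(seqid, from, to, family_id, engine,
                             evalue, bitscore, hsp_length, coverage) {
  minus <- from > to
  lo <- pmin(from, to); hi <- pmax(from, to)
  data.frame(seqid = seqid, start = as.integer(lo - 1L), end = as.integer(hi),
             strand = ifelse(minus, "-", "+"),
             family_id = family_id, engine = engine,
             evalue = evalue, bitscore = bitscore,
             hsp_length = as.integer(hsp_length), coverage = coverage,
             stringsAsFactors = FALSE)
}

candidate_gr <- function(candidates, source = "mirhom") {
  gr <- as_granges0(candidates)
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- "pre_miRNA"
  S4Vectors::mcols(gr)$ID <- candidates$id
  S4Vectors::mcols(gr)$family <- candidates$family_id
  if (!is.null(candidates$confidence))
    S4Vectors::mcols(gr)$confidence <- candidates$confidence
  if (!is.null(candidates$status))
    S4Vectors::mcols(gr)$status <- candidates$status
  if (!is.null(candidates$evidence))
    S4Vectors::mcols(gr)$evidence <- candidates$evidence
  gr
}

check_bounds <- function(candidates, seq_lengths) {
  if (is.null(seq_lengths)) return(invisible())
  len <- seq_lengths[candidates$seqid]
  bad <- which(is.na(len) | candidates$end > len)
  if (length(bad))
    stop("candidate '", candidates$id[bad[1]],
         "' exceeds the length of sequence ", candidates$seqid[bad[1]])
  invisible()
}

#' Write candidates as GFF3 (1-based inclusive)
#'
#' @param candidates data.frame with seqid/start/end/strand (internal 0-based
#'   half-open), id, family_id and optionally confidence, status, evidence
#' @param path output file
#' @param seq_lengths optional named vector of target sequence lengths; a
#'   candidate extending past its sequence is refused
#' @export
write_gff3 <- function(candidates, path, seq_lengths = NULL) {
  if (nrow(candidates) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  check_bounds(candidates, seq_lengths)
  rtracklayer::export(candidate_gr(candidates), path, format = "gff3")
  invisible(path)
}

#' Write candidates as BED6 (0-based half-open)
#' @inheritParams write_gff3
#' @export
write_bed <- function(candidates, path, seq_lengths = NULL) {
  if (nrow(candidates) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  check_bounds(candidates, seq_lengths)
  gr <- as_granges0(candidates)
  S4Vectors::mcols(gr)$name <- candidates$id
  score <- if (!is.null(candidates$best_bitscore))
    pmin(1000, pmax(0, round(candidates$best_bitscore))) else 0L
  S4Vectors::mcols(gr)$score <- score
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write candidate precursor sequences as FASTA, excised from the genome
#'
#' Minus-strand candidates are reverse-complemented so the written sequence
#' is the precursor in 5'->3' orientation.
#'
#' @param candidates candidate data.frame (internal coordinates)
#' @param genome named character vector of target sequences (DNA)
#' @param path output file
#' @export
write_candidate_fasta <- function(candidates, genome, path) {
  check_bounds(candidates, setNames(nchar(genome), names(genome)))
  seqs <- vapply(seq_len(nrow(candidates)), function(i)
    extract_sequence(genome, candidates[i, ]), "")
  ids <- sprintf("%s %s;family=%s", candidates$id,
                 format_locus(candidates), candidates$family_id)
  write_fasta(setNames(seqs, ids), path)
}

format_locus <- function(df)
  sprintf("%s:%d-%d(%s)", df$seqid, df$start, df$end, df$strand)

#' Excise one interval from the genome, strand-aware (5'->3')
#' @keywords internal
extract_sequence <- function(genome, iv) {
  s <- substr(genome[[iv$seqid]], iv$start + 1L, iv$end)
  if (iv$strand == "-") reverse_complement(s) else s
}

#' Reverse complement of a DNA string
#' @param x character scalar over A,C,G,T,N
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read a GFF3 or BED annotation into the internal interval convention
#'
#' @param path GFF3 (.gff/.gff3) or BED file
#' @return data.frame seqid/start/end/strand (0-based half-open) plus any
#'   attribute columns present (ID, family, confidence, ...)
#' @export
read_annotation <- function(path) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  df <- data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  meta <- as.data.frame(S4Vectors::mcols(gr))
  for (col in intersect(c("ID", "name", "family", "confidence", "status",
                          "type", "evidence"), names(meta)))
    df[[col]] <- as.character(meta[[col]])
  df
}

#' Parse a Stockholm alignment (single-line or interleaved)
#'
#' Only sequence rows and the `#=GC SS_cons` line are interpreted; other
#' `#=GF/#=GS/#=GR/#=GC` annotations are preserved opaquely. The `#=GF AC`
#' or `#=GF ID` field provides the family id when present.
#'
#' @param path Stockholm file
#' @return list with elements `family_id`, `rows` (named character, aligned,
#'   gap '-'), `ss_cons` (dot-bracket of alignment length), `gf` (opaque
#'   annotation lines)
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path)
  rows <- list(); ss <- character(0); gf <- character(0); fam <- NA_character_
  for (ln in lines[-1]) {
    t <- trimws(ln)
    if (!nzchar(t) || t == "//") next
    if (startsWith(t, "#=GC")) {
      p <- strsplit(t, "\\s+")[[1]]
      if (length(p) >= 3 && p[2] == "SS_cons") ss <- c(ss, p[3])
      else gf <- c(gf, t)
    } else if (startsWith(t, "#=GF")) {
      p <- strsplit(t, "\\s+")[[1]]
      if (length(p) >= 3 && p[2] %in% c("AC", "ID") && is.na(fam)) fam <- p[3]
      gf <- c(gf, t)
    } else if (startsWith(t, "#")) {
      gf <- c(gf, t)
    } else {
      p <- strsplit(t, "\\s+")[[1]]
      if (length(p) != 2)
        stop("malformed Stockholm sequence row: ", t)
      nm <- p[1]
      rows[[nm]] <- paste0(if (is.null(rows[[nm]])) "" else rows[[nm]], p[2])
    }
  }
  rows <- vapply(rows, function(s) toupper(chartr(".", "-", s)), "")
  ss_cons <- paste(ss, collapse = "")
  ss_cons <- normalize_ss(ss_cons)
  if (length(rows)) {
    w <- unique(nchar(rows))
    if (length(w) != 1L)
      stop("Stockholm rows have unequal aligned lengths")
    if (nzchar(ss_cons) && nchar(ss_cons) != w)
      stop("SS_cons length does not match alignment length")
  }
  if (nzchar(ss_cons)) parse_dotbracket(ss_cons)  # validate balance
  list(family_id = if (is.na(fam)) tools::file_path_sans_ext(basename(path)) else fam,
       rows = rows, ss_cons = ss_cons, gf = gf)
}

# Map WUSS/Rfam consensus annotation onto plain dot-bracket.
normalize_ss <- function(ss) {
  ss <- chartr("<>[]{}", "()()()", ss)
  gsub("[^()]", ".", ss)
}

#' Write a Stockholm alignment with `#=GC SS_cons`
#' @param aln list as returned by [read_stockholm()]
#' @param path output file
#' @export
write_stockholm <- function(aln, path) {
  nm <- names(aln$rows)
  w <- max(nchar(c(nm, "#=GC SS_cons"))) + 2L
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  writeLines(sprintf("#=GF ID %s", aln$family_id), con)
  for (i in seq_along(aln$rows))
    writeLines(sprintf("%-*s%s", w, nm[i], aln$rows[[i]]), con)
  if (nzchar(aln$ss_cons))
    writeLines(sprintf("%-*s%s", w, "#=GC SS_cons", aln$ss_cons), con)
  writeLines("//", con)
  invisible(path)
}
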