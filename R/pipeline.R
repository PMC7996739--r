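#' Run the full annotation workflow: homology -> mature placement -> evaluation
#'
#' Every homology-stage candidate region ends up in exactly one of three
#' buckets: `accepted` (with a High/Medium confidence), `discarded` (with a
#' machine-readable reject reason, including strand rejections) or
#' `potential` (beyond the per-family bitscore cap). A per-candidate filter
#' log records each threshold with the observed value.
#'
#' @param genome named character vector of target sequences, or a FASTA path
#' @param families list of [mirna_family()] objects, or a directory of
#'   per-family subdirectories (see [read_family()]); families without
#'   mature sequences are skipped with a warning
#' @param hits named list of hit tables (names among "blast", "hmm", "cm"),
#'   as returned by [read_tabular_hits()]; and/or set `engines` to run
#'   searches live
#' @param config see [default_config()]
#' @param engines character subset of c("blast", "hmm") to execute via the
#'   installed blastn/nhmmer binaries (optional; hit tables may be supplied
#'   instead)
#' @param outdir if non-NULL, write accepted.gff3/.bed/.fa, discarded.tsv,
#'   potential.tsv, summary.tsv and filters.tsv there
#' @return list: `accepted`, `discarded`, `potential` (candidate data
#'   frames), `summary` (per-family counts), `filter_log`
#' @export
run_annotate <- function(genome, families, hits = list(),
                         config = default_config(), engines = character(0),
                         outdir = NULL) {
  check_fold_engine()
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  if (is.character(families) && length(families) == 1L) {
    dirs <- list.dirs(families, recursive = FALSE)
    families <- Filter(Negate(is.null), lapply(dirs, read_family))
    names(families) <- vapply(families, `[[`, "", "family_id")
  }
  if (length(families) == 0L) stop("no usable family bundles")
  genome_size <- if (!is.null(config$genome_size)) config$genome_size
                 else sum(nchar(genome))
  for (eng in engines)
    hits[[eng]] <- rbind(hits[[eng]],
                         run_engine(eng, genome, families, config))
  if (length(hits) == 0L)
    stop("no search path available: supply pre-computed hits or engines")

  accepted <- list(); discarded <- list(); potential <- list()
  per_family <- list(); flog <- list()
  log_filter <- function(id, filter, threshold, observed, pass)
    flog[[length(flog) + 1L]] <<- data.frame(
      candidate = id, filter = filter, threshold = as.character(threshold),
      observed = as.character(observed), pass = pass)

  for (fam in names(families)) {
    family <- families[[fam]]
    if (is.null(family$matures) || nrow(family$matures) == 0L) {
      warning("family ", fam, " has no mature sequences; skipped")
      next
    }
    cutoffs <- family$cutoffs
    if (is.null(cutoffs)) cutoffs <- family_cutoffs(NULL, genome_size)
    fam_hits <- lapply(hits, function(h) h[h$family_id == fam, , drop = FALSE])
    regions <- list()
    if (!is.null(fam_hits$blast) && nrow(fam_hits$blast))
      regions$blast <- merge_hits_to_regions(
        filter_sequence_hits(fam_hits$blast, config))
    if (!is.null(fam_hits$hmm) && nrow(fam_hits$hmm))
      regions$hmm <- merge_hits_to_regions(
        filter_hmm_hits(fam_hits$hmm, config))
    if (!is.null(fam_hits$cm) && nrow(fam_hits$cm))
      regions$cm <- merge_hits_to_regions(
        filter_cm_hits(fam_hits$cm, cutoffs, config))
    regions <- lapply(regions, disambiguate_strands)
    merged <- do.call(merge_engines, unname(regions))
    merged <- disambiguate_strands(merged)
    capped <- cap_candidates(merged, config$candidate_cap)
    pot <- capped$potential
    pending <- capped$processed
    n_homology <- nrow(pending) + nrow(pot)

    fam_acc <- list(); fam_disc <- list()
    cand_i <- 0L
    for (k in seq_len(nrow(pending))) {
      region <- pending[k, , drop = FALSE]
      cand_i <- cand_i + 1L
      id <- sprintf("%s_cand%03d", fam, cand_i)
      if (region$status == "rejected_strand") {
        region$id <- id; region$reject_reason <- "rejected_strand"
        fam_disc[[length(fam_disc) + 1L]] <- region
        next
      }
      evd <- paste(sort(unique(region$hits[[1]]$engine)), collapse = ",")
      cand <- evaluate_region(region, family, genome, config)
      res <- cand$result
      row <- cand$interval
      row$id <- id; row$family_id <- fam
      row$best_bitscore <- region$best_bitscore
      row$evidence <- evd
      log_filter(id, "length", config$max_precursor_length,
                 row$end - row$start, isTRUE(res$length_ok))
      if (!is.na(res$mfe))
        log_filter(id, "mfe", config$mfe_threshold, res$mfe,
                   isTRUE(res$mfe_ok))
      if (!is.na(res$arm_verdict))
        log_filter(id, "arm", "valid", res$arm_verdict,
                   res$arm_verdict == "valid")
      if (!is.na(res$ted))
        log_filter(id, "ted", config$ted_threshold, res$ted,
                   res$ted <= config$ted_threshold)
      if (res$final_status == "accepted") {
        row$confidence <- res$confidence
        row$status <- "accepted"
        row$ted <- res$ted
        fam_acc[[length(fam_acc) + 1L]] <- row
      } else {
        row$status <- "discarded"
        row$reject_reason <- res$reject_reason
        fam_disc[[length(fam_disc) + 1L]] <- row
      }
    }
    acc <- bind_candidate_rows(fam_acc)
    disc <- bind_candidate_rows(fam_disc)
    accepted[[fam]] <- acc; discarded[[fam]] <- disc; potential[[fam]] <- pot
    per_family[[fam]] <- data.frame(
      Family = fam, Homology = n_homology, Final = nrow(acc),
      Filtered = nrow(disc), Potential = nrow(pot),
      High = sum(acc$confidence == "High"),
      Medium = sum(acc$confidence == "Medium"))
  }
  out <- list(
    accepted = bind_candidate_rows(accepted),
    discarded = bind_candidate_rows(discarded),
    potential = do.call(rbind, c(potential, list(empty_regions()))),
    summary = do.call(rbind, per_family),
    filter_log = do.call(rbind, c(flog, list(NULL))))
  rownames(out$summary) <- NULL
  if (!is.null(outdir)) write_run_outputs(out, genome, outdir)
  out
}

bind_candidate_rows <- function(rows) {
  rows <- Filter(function(x) !is.null(x) && nrow(x) > 0L, rows)
  if (!length(rows)) {
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      id = character(0), family_id = character(0),
                      confidence = character(0), status = character(0),
                      reject_reason = character(0),
                      stringsAsFactors = FALSE))
  }
  cols <- unique(unlist(lapply(rows, names)))
  cols <- setdiff(cols, "hits")
  rows <- lapply(rows, function(r) {
    for (m in setdiff(cols, names(r))) r[[m]] <- NA
    r[, cols, drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Mature placement + trimming + structural evaluation for one region.
evaluate_region <- function(region, family, genome, config) {
  chrom_len <- nchar(genome[[region$seqid]])
  iv <- region[, c("seqid", "start", "end", "strand")]
  # widen very short regions so placement has context to work with
  if (iv$end - iv$start < 40L) {
    pad <- ceiling((40L - (iv$end - iv$start)) / 2) + 5L
    iv$start <- max(0L, iv$start - pad)
    iv$end <- min(chrom_len, iv$end + pad)
  }
  seq0 <- extract_sequence(genome, iv)
  placement <- locate_mature(seq0, family, config)
  if (is.null(placement))
    return(list(interval = iv,
                result = evaluate_candidate(seq0, NULL, family, config)))
  trimmed <- trim_precursor(iv, placement, config$flank, chrom_len)
  seq1 <- extract_sequence(genome, trimmed)
  placement <- locate_mature(seq1, family, config)
  list(interval = trimmed,
       result = evaluate_candidate(seq1, placement, family, config))
}

write_run_outputs <- function(out, genome, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seq_lengths <- setNames(nchar(genome), names(genome))
  write_gff3(out$accepted, file.path(outdir, "accepted.gff3"), seq_lengths)
  write_bed(out$accepted, file.path(outdir, "accepted.bed"), seq_lengths)
  if (nrow(out$accepted))
    write_candidate_fasta(out$accepted, genome,
                          file.path(outdir, "accepted.fa"))
  write_tsv <- function(df, name) {
    df <- df[, setdiff(names(df), "hits"), drop = FALSE]
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(out$discarded, "discarded.tsv")
  pot <- out$potential
  if (!is.null(pot)) write_tsv(pot, "potential.tsv")
  if (!is.null(out$summary)) write_tsv(out$summary, "summary.tsv")
  if (!is.null(out$filter_log)) write_tsv(out$filter_log, "filters.tsv")
  invisible(outdir)
}

# Live search adapters. blastn: tabular outfmt 6 against a temporary
# database; nhmmer would require per-family HMM files, so it consumes a
# pre-built <family>.hmm next to the family bundle when present.
run_engine <- function(engine, genome, families, config) {
  if (engine == "blast") run_blastn(genome, families)
  else if (engine == "hmm") stop("live nhmmer runs need family HMM files; ",
                                 "supply nhmmer --tblout output as hits instead")
  else stop("unknown engine: ", engine)
}

run_blastn <- function(genome, families) {
  for (tool in c("makeblastdb", "blastn"))
    if (!nzchar(Sys.which(tool)))
      stop("requested blast mode but '", tool, "' is not on PATH")
  td <- tempfile("blastdb"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  gpath <- file.path(td, "genome.fa")
  write_fasta(genome, gpath)
  system2("makeblastdb", c("-in", gpath, "-dbtype", "nucl"),
          stdout = FALSE, stderr = FALSE)
  qpath <- file.path(td, "queries.fa")
  qseqs <- do.call(c, unname(lapply(families, function(f) {
    rows <- gsub("-", "", f$alignment$rows, fixed = TRUE)
    setNames(gsub("U", "T", rows, fixed = TRUE),
             paste0(f$family_id, "|", names(rows)))
  })))
  write_fasta(qseqs, qpath)
  opath <- file.path(td, "hits.tab6")
  system2("blastn", c("-task", "blastn-short", "-db", gpath, "-query", qpath,
                      "-outfmt", "6", "-evalue", "0.05", "-out", opath),
          stdout = FALSE, stderr = FALSE)
  qf <- setNames(sub("\\|.*$", "", names(qseqs)), names(qseqs))
  read_tabular_hits(opath, "blast-tab6",
                    query_lengths = setNames(nchar(qseqs), names(qseqs)),
                    query_family = qf)
}

#' Compare pipeline output with a reference annotation
#'
#' Thin wrapper over [classify_loci()], [classify_family_overlap()] and
#' [annotate_additional()].
#'
#' @param candidates accepted-candidate data.frame or GFF3/BED path
#' @param reference reference annotation data.frame or GFF3/BED path
#' @param aux optional auxiliary annotation (data.frame or path) for
#'   categorizing Additional candidates
#' @param outdir if non-NULL, write comparison.tsv and classes.tsv there
#' @return list: `summary` (one row, benchmark column set), `reference`
#'   and `candidates` with per-locus classes, `family_overlap` (per-family
#'   Perfect/Partial/Without), `additional_categories`
#' @export
run_evaluate <- function(candidates, reference, aux = NULL, outdir = NULL) {
  if (is.character(candidates)) candidates <- read_annotation(candidates)
  if (is.character(reference)) reference <- read_annotation(reference)
  if (is.character(aux)) aux <- read_annotation(aux)
  cls <- classify_loci(candidates, reference)
  fam_overlap <- NULL
  ref <- cls$reference
  if (!is.null(ref$family) && nrow(ref)) {
    agg <- stats::aggregate(ref$class == "Match",
                            by = list(family = ref$family), FUN = sum)
    tot <- stats::aggregate(rep(1L, nrow(ref)),
                            by = list(family = ref$family), FUN = sum)
    fam_overlap <- data.frame(
      family = agg$family, n_matched = agg$x, n_annotated = tot$x,
      class = classify_family_overlap(agg$x, tot$x))
  }
  add_idx <- which(cls$candidates$class == "Additional")
  add_cat <- annotate_additional(cls$candidates[add_idx, , drop = FALSE], aux)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(cls$summary, file.path(outdir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(summary = cls$summary, reference = cls$reference,
       candidates = cls$candidates, family_overlap = fam_overlap,
       additional_categories = add_cat)
}
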