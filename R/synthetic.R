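#' Synthetic miRNA test worlds
#'
#' Generators for fully self-contained toy datasets: precursor hairpins
#' with known mature arms, sibling families with a consensus structure,
#' dinucleotide-shuffled decoys, toy genomes with implanted loci, and
#' point-mutation series. All randomness is drawn from R's global
#' Mersenne-Twister stream; `set.seed()` before any generator gives full
#' determinism.
#'
#' @name synthetic
NULL

rna_bases <- c("A", "C", "G", "U")
rc_rna <- c(A = "U", C = "G", G = "C", U = "A")

#' Generate one miRNA-like hairpin precursor
#'
#' The sequence is a stem + loop + reverse complement of the stem, with
#' roughly 10% of stem positions perturbed into GU wobbles or single-base
#' bulges. The miR is a 22-nt window on the 5' arm; the miR* is its
#' base-paired window on the 3' arm. The construction is verified by
#' folding: a draw whose MFE structure exceeds -10 kcal/mol or whose arm
#' placement is not `valid` is regenerated (bounded at 100 tries).
#'
#' @param stem_len stem length in pairs, in [25, 45]
#' @param loop_len loop length in nt, in [4, 15]
#' @return list: `sequence` (RNA), `dotbracket` (construction structure),
#'   `mir`, `mirstar` (0-based half-open intervals on the sequence),
#'   `mir_seq`, `mirstar_seq`
#' @export
make_hairpin <- function(stem_len, loop_len) {
  stopifnot(stem_len >= 25L, stem_len <= 45L, loop_len >= 4L, loop_len <= 15L)
  for (try in seq_len(100L)) {
    hp <- draw_hairpin(stem_len, loop_len)
    fold <- fold_mfe(hp$sequence)
    if (fold$mfe > -10) next
    placement <- structure(list(precursor_sequence = hp$sequence,
                                mir_interval = hp$mir,
                                mirstar_interval = hp$mirstar,
                                mir_arm = "5p"),
                           class = "mature_placement")
    if (check_arm_consistency(placement, fold) == "valid") return(hp)
  }
  stop("could not generate a valid hairpin in 100 tries")
}

draw_hairpin <- function(stem_len, loop_len) {
  five <- character(0); three <- character(0)   # three built loop-outward
  pairs5 <- integer(0); pairs3 <- integer(0)
  for (i in seq_len(stem_len)) {
    r <- stats::runif(1)
    if (r < 0.04) {                      # bulge on the 5' arm
      five <- c(five, sample(rna_bases, 1))
    } else if (r < 0.08) {               # bulge on the 3' arm
      three <- c(sample(rna_bases, 1), three)
    } else if (r < 0.13) {               # GU wobble pair
      gu <- sample(c("G", "U"), 1)
      five <- c(five, gu)
      three <- c(if (gu == "G") "U" else "G", three)
      pairs5 <- c(pairs5, length(five)); pairs3 <- c(pairs3, length(three))
    } else {                             # Watson-Crick pair, GC-leaning
      x <- sample(rna_bases, 1, prob = c(0.2, 0.3, 0.3, 0.2))
      five <- c(five, x)
      three <- c(rc_rna[[x]], three)
      pairs5 <- c(pairs5, length(five)); pairs3 <- c(pairs3, length(three))
    }
  }
  loop <- sample(rna_bases, loop_len, replace = TRUE)
  n5 <- length(five); nl <- loop_len; n3 <- length(three)
  seqc <- c(five, loop, three)
  db <- rep(".", length(seqc))
  db[pairs5] <- "("
  db[n5 + nl + (n3 + 1L) - pairs3] <- ")"
  # miR: 22-nt window on the 5' arm, offset 2 from the precursor start
  mir <- c(2L, 24L)
  # miR*: the base-paired window on the 3' arm (construction pairs)
  in_mir <- pairs5 > mir[1] & pairs5 <= mir[2]
  partners <- (n5 + nl + n3 + 1L) - pairs3[in_mir]
  mirstar <- c(min(partners) - 1L, max(partners))
  list(sequence = paste(seqc, collapse = ""),
       dotbracket = paste(db, collapse = ""),
       mir = mir, mirstar = as.integer(mirstar),
       mir_seq = paste(seqc[(mir[1] + 1L):mir[2]], collapse = ""),
       mirstar_seq = paste(seqc[(mirstar[1] + 1L):mirstar[2]], collapse = ""))
}

#' Dinucleotide-preserving sequence shuffle (Altschul-Erikson)
#'
#' Permutes a sequence while preserving its exact dinucleotide counts,
#' which destroys secondary structure without changing the composition
#' features that folding energies are most sensitive to.
#'
#' @param sequence character scalar
#' @return shuffled sequence with identical dinucleotide counts
#' @export
dinucleotide_shuffle <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  if (n < 3L) return(sequence)
  verts <- unique(ch)
  succ <- split(ch[-1], factor(ch[-n], levels = verts))
  zfin <- ch[n]
  for (try in seq_len(1000L)) {
    last <- vapply(verts, function(v) {
      e <- succ[[v]]
      if (v == zfin || length(e) == 0L) NA_character_
      else e[sample.int(length(e), 1L)]
    }, "")
    # tree check: following the chosen last edges must reach the final vertex
    ok <- TRUE
    for (v in verts) {
      if (v == zfin || is.na(last[[v]])) next
      seen <- character(0); cur <- v
      while (cur != zfin) {
        if (cur %in% seen || is.na(last[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur); cur <- last[[cur]]
      }
      if (!ok) break
    }
    if (!ok) next
    ordered <- lapply(verts, function(v) {
      e <- succ[[v]]
      if (length(e) == 0L) return(e)
      if (v == zfin) return(if (length(e) > 1L) sample(e) else e)
      i <- match(last[[v]], e)
      rest <- e[-i]
      c(if (length(rest)) sample(rest) else character(0), e[i])
    })
    names(ordered) <- verts
    out <- character(n); out[1] <- ch[1]
    ptr <- setNames(rep(1L, length(verts)), verts)
    cur <- ch[1]
    for (k in 2:n) {
      nxt <- ordered[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      out[k] <- nxt; cur <- nxt
    }
    return(paste(out, collapse = ""))
  }
  stop("dinucleotide shuffle failed to find an Eulerian ordering")
}

#' Build a synthetic family bundle around a hairpin
#'
#' The family alignment consists of `n_members` siblings: copies of the
#' hairpin carrying `n_mut` random substitutions each (gap-free, so the
#' alignment is trivial); SS_cons is the construction structure. The
#' matures are the hairpin's miR (5p) and miR* (3p).
#'
#' @param family_id family name
#' @param hairpin [make_hairpin()] result
#' @param n_members number of siblings (default 5)
#' @param n_mut substitutions per sibling (default 3)
#' @export
make_family <- function(family_id, hairpin, n_members = 5L, n_mut = 3L) {
  rows <- vapply(seq_len(n_members), function(i)
    substitute_positions(hairpin$sequence, n_mut), "")
  names(rows) <- sprintf("%s_m%d", family_id, seq_len(n_members))
  aln <- list(family_id = family_id, rows = rows,
              ss_cons = hairpin$dotbracket, gf = character(0))
  matures <- data.frame(
    id = paste0(family_id, c("-5p", "-3p")),
    seq = c(hairpin$mir_seq, hairpin$mirstar_seq),
    arm = c("5p", "3p"), stringsAsFactors = FALSE)
  mirna_family(family_id, aln, matures)
}

substitute_positions <- function(sequence, k) {
  ch <- strsplit(sequence, "")[[1]]
  pos <- sample.int(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(rna_bases, ch[p]), 1)
  paste(ch, collapse = "")
}

#' Apply an increasing, nested series of point mutations
#'
#' For each k in `counts`, exactly k distinct positions are substituted to
#' a different base; mutations accumulate along the series, mirroring an
#' increasing mismatch load on the same locus.
#'
#' @param sequence locus sequence
#' @param counts non-decreasing integer vector of mutation counts
#' @return character vector of mutated sequences, one per count
#' @export
mutation_series <- function(sequence, counts) {
  stopifnot(!is.unsorted(counts), all(counts >= 0L))
  ch <- strsplit(sequence, "")[[1]]
  kmax <- max(counts)
  if (kmax > length(ch)) stop("more mutations than positions")
  alphabet <- if (any(ch == "T")) c("A", "C", "G", "T") else rna_bases
  pos <- sample.int(length(ch), kmax)
  subs <- vapply(pos, function(p) sample(setdiff(alphabet, ch[p]), 1), "")
  vapply(counts, function(k) {
    m <- ch
    if (k > 0L) m[pos[seq_len(k)]] <- subs[seq_len(k)]
    paste(m, collapse = "")
  }, "")
}

#' Simulate a toy genome with implanted hairpins and decoys
#'
#' Builds an i.i.d.-uniform background genome, implants `n_hairpins`
#' precursor hairpins (each its own family) at non-overlapping uniform
#' random positions on random strands, and implants `n_decoys`
#' dinucleotide-shuffled copies of those hairpins as structure-free
#' decoys. Emulated blast-tab6 homology hits covering every implanted
#' locus (true and decoy) are included, so the full filter cascade can run
#' without any search engine.
#'
#' @param genome_length background genome length in nt (default 1e6)
#' @param n_hairpins implanted true precursors (default 20)
#' @param n_decoys implanted shuffled decoys (default 20)
#' @param seed RNG seed (stored in the world)
#' @return a `synthetic_world`: list with `genome` (named DNA string),
#'   `truth` and `decoys` (interval data.frames with `id`, `family_id`),
#'   `families` (list of [mirna_family()]), `hairpins`, `hits_blast`
#'   (hit table), `seed`
#' @export
simulate_world <- function(genome_length = 1e6, n_hairpins = 20L,
                           n_decoys = 20L, seed = 1L) {
  set.seed(seed)
  hairpins <- lapply(seq_len(n_hairpins), function(i)
    make_hairpin(sample(25:45, 1), sample(4:15, 1)))
  fams <- sprintf("synfam%02d", seq_len(n_hairpins))
  families <- lapply(seq_len(n_hairpins), function(i)
    make_family(fams[i], hairpins[[i]]))
  names(families) <- fams
  decoy_seqs <- if (n_decoys > 0L)
    vapply(seq_len(n_decoys), function(i)
      dinucleotide_shuffle(hairpins[[(i - 1L) %% n_hairpins + 1L]]$sequence),
      "") else character(0)
  inserts <- c(vapply(hairpins, `[[`, "", "sequence"), decoy_seqs)
  inserts <- gsub("U", "T", inserts, fixed = TRUE)
  lens <- nchar(inserts)
  n_ins <- length(inserts)
  margin <- 60L
  # non-overlapping placement
  for (try in seq_len(100L)) {
    starts <- sort(sample.int(genome_length - max(lens) - margin, n_ins))
    if (n_ins <= 1L || all(diff(starts) > max(lens) + margin)) break
    if (try == 100L) stop("genome too small for requested implants")
  }
  strands <- sample(c("+", "-"), n_ins, replace = TRUE)
  genome <- paste(sample(c("A", "C", "G", "T"), genome_length, replace = TRUE),
                  collapse = "")
  for (i in seq_len(n_ins)) {
    s <- if (strands[i] == "-") reverse_complement(inserts[i]) else inserts[i]
    substr(genome, starts[i] + 1L, starts[i] + lens[i]) <- s
  }
  fam_of <- c(fams, fams[((seq_len(n_decoys) - 1L) %% n_hairpins) + 1L])
  loci <- genomic_interval("chr1", starts, starts + lens, strands)
  loci$family_id <- fam_of
  loci$id <- c(sprintf("true%02d", seq_len(n_hairpins)),
               if (n_decoys > 0L) sprintf("decoy%02d", seq_len(n_decoys)))
  truth <- loci[seq_len(n_hairpins), , drop = FALSE]
  decoys <- if (n_decoys > 0L) loci[-seq_len(n_hairpins), , drop = FALSE]
            else loci[0, , drop = FALSE]
  structure(list(genome = c(chr1 = genome), truth = truth, decoys = decoys,
                 families = families, hairpins = hairpins,
                 hits_blast = emulate_blast_hits(loci, families),
                 seed = seed),
            class = "synthetic_world")
}

# Two overlapping HSPs per implanted locus, in the internal hit format,
# as an ultra-sensitive pairwise search would report them.
emulate_blast_hits <- function(loci, families) {
  out <- lapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    qlen <- nchar(gsub("-", "", families[[l$family_id]]$alignment$rows[[1]],
                       fixed = TRUE))
    len <- l$end - l$start
    cut <- as.integer(round(len * 0.75))
    true_locus <- startsWith(l$id, "true")
    bit <- if (true_locus) 1.8 * len else 1.2 * len
    ev <- if (true_locus) 1e-25 else 1e-8
    data.frame(seqid = l$seqid,
               start = c(l$start, l$start + as.integer(round(len * 0.25))),
               end = c(l$start + cut, l$end),
               strand = l$strand, family_id = l$family_id, engine = "blast",
               evalue = ev, bitscore = c(bit, 0.9 * bit),
               hsp_length = c(cut, len - as.integer(round(len * 0.25))),
               coverage = c(cut, len - as.integer(round(len * 0.25))) / qlen,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a synthetic world to disk
#'
#' Produces `genome.fa`, `truth.gff3`, `decoys.gff3`, one directory per
#' family under `families/` (Stockholm + mature FASTA) and emulated hits
#' under `hits/blast.tab6`.
#'
#' @param world [simulate_world()] result
#' @param outdir output directory (created)
#' @export
write_world <- function(world, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(world$genome, file.path(outdir, "genome.fa"))
  tr <- world$truth; tr$confidence <- NA; tr$status <- "truth"
  write_gff3(tr, file.path(outdir, "truth.gff3"))
  if (nrow(world$decoys)) {
    de <- world$decoys; de$status <- "decoy"
    write_gff3(de, file.path(outdir, "decoys.gff3"))
  }
  for (fam in names(world$families)) {
    f <- world$families[[fam]]
    fdir <- file.path(outdir, "families", fam)
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    write_stockholm(f$alignment, file.path(fdir, paste0(fam, ".stk")))
    write_fasta(setNames(f$matures$seq, f$matures$id),
                file.path(fdir, paste0(fam, ".mature.fa")))
  }
  dir.create(file.path(outdir, "hits"), showWarnings = FALSE)
  write_blast_tab6(world$hits_blast, world$families,
                   file.path(outdir, "hits", "blast.tab6"))
  invisible(outdir)
}

# Serialize internal hits back into blast -outfmt 6 (1-based inclusive,
# minus strand as sstart > send), the format read_tabular_hits consumes.
write_blast_tab6 <- function(hits, families, path) {
  qlen <- vapply(hits$family_id, function(f)
    nchar(gsub("-", "", families[[f]]$alignment$rows[[1]], fixed = TRUE)), 0)
  alen <- hits$hsp_length
  qstart <- rep(1L, nrow(hits)); qend <- pmin(alen, qlen)
  sstart <- ifelse(hits$strand == "+", hits$start + 1L, hits$end)
  send <- ifelse(hits$strand == "+", hits$end, hits$start + 1L)
  lines <- sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2g\t%.1f",
                   hits$family_id, hits$seqid, 95.0, alen, 2L, 0L,
                   qstart, qend, sstart, send, hits$evalue, hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}
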