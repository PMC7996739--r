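toy_family <- function(mature = "ACGUACGUACGUACGUACGUAC", id = "toy-5p",
                       extra = NULL) {
  matures <- data.frame(id = c(id, extra$id),
                        seq = c(mature, extra$seq),
                        stringsAsFactors = FALSE)
  aln <- list(family_id = "toy",
              rows = c(m1 = paste0(strrep("A", 10), mature, strrep("A", 20))),
              ss_cons = strrep(".", 10 + nchar(mature) + 20),
              gf = character(0))
  mirna_family("toy", aln, matures)
}

test_that("an exact mature copy is located at its offset with full score", {
  mat <- "ACGUACGUACGUACGUACGUAC"  # 22 nt
  prec <- paste0(strrep("G", 10), mat, strrep("C", 30))
  pl <- locate_mature(prec, toy_family(mat))
  expect_s3_class(pl, "mature_placement")
  expect_equal(pl$mir_interval, c(10L, 32L))
  expect_equal(pl$alignment_score, 22)
  expect_equal(pl$source_mature_id, "toy-5p")
})

test_that("a precursor without any scoring window fails with no mature anchor", {
  pl <- locate_mature(strrep("A", 60), toy_family("GCGCGCGCGCGCGCGCGCGC"))
  expect_null(pl)
})

test_that("arm hints parse from miRBase-style id suffixes", {
  fam <- mirna_family("f", list(family_id = "f", rows = c(a = "ACGU"),
                                ss_cons = "....", gf = character(0)),
                      data.frame(id = c("hsa-x-5p", "hsa-x-3p", "hsa-x"),
                                 seq = rep("ACGUACGUACGUACGUACGU", 3)))
  expect_equal(fam$matures$arm, c("5p", "3p", "unknown"))
  expect_error(mirna_family("f", NULL,
                            data.frame(id = "a", seq = "ACGU")), "15")
})

test_that("a mature aligning equally on both arms takes the 5'-most placement", {
  mat <- "ACGUACGUACGUACGUACGUAC"
  # the same window twice; exhaustive ungapped scan confirms two optima
  prec <- paste0("GGGG", mat, strrep("G", 12), mat, "GGGG")
  scores <- vapply(0:(nchar(prec) - nchar(mat)), function(o) {
    win <- substr(prec, o + 1, o + nchar(mat))
    sum(strsplit(win, "")[[1]] == strsplit(mat, "")[[1]]) -
      sum(strsplit(win, "")[[1]] != strsplit(mat, "")[[1]])
  }, 0)
  best_offsets <- which(scores == max(scores)) - 1L
  expect_length(best_offsets, 2L)
  expect_message(pl <- locate_mature(prec, toy_family(mat)), "equally|keeping")
  expect_equal(pl$mir_interval[1], best_offsets[1])
})

test_that("placement recovers both arms of a constructed hairpin", {
  set.seed(9)
  hp <- make_hairpin(32, 8)
  fam <- make_family("famZ", hp)
  pl <- locate_mature(hp$sequence, fam)
  expect_equal(pl$mir_interval, hp$mir)
  expect_equal(pl$mirstar_interval, hp$mirstar)
  expect_equal(pl$mir_arm, "5p")
})

test_that("miR* is predicted from the fold when no annotated star aligns", {
  set.seed(10)
  hp <- make_hairpin(30, 6)
  fam5only <- mirna_family("f5", list(family_id = "f5",
                                      rows = c(m1 = hp$sequence),
                                      ss_cons = hp$dotbracket,
                                      gf = character(0)),
                           data.frame(id = "f5-5p", seq = hp$mir_seq))
  pl <- locate_mature(hp$sequence, fam5only)
  expect_false(is.null(pl$mirstar_interval))
  # predicted star sits on the 3' arm, disjoint from the miR
  expect_gte(pl$mirstar_interval[1], pl$mir_interval[2])
  # close to the construction star (pairing-register shifts allowed)
  expect_lt(abs(pl$mirstar_interval[1] - hp$mirstar[1]), 6L)
})

test_that("trimming spans the matures plus flank, clipped at the chromosome", {
  iv <- genomic_interval("chr1", 1000L, 1100L, "+")
  pl <- structure(list(mir_interval = c(10L, 32L),
                       mirstar_interval = c(60L, 82L), mir_arm = "5p"),
                  class = "mature_placement")
  tr <- trim_precursor(iv, pl, flank = 10L, chrom_length = 10000L)
  expect_equal(c(tr$start, tr$end), c(1000L, 1092L))
  # clipping at the chromosome start
  iv0 <- genomic_interval("chr1", 5L, 105L, "+")
  tr0 <- trim_precursor(iv0, pl, flank = 20L, chrom_length = 10000L)
  expect_equal(tr0$start, 0L)
  # minus strand: local coordinates count from the other end
  ivm <- genomic_interval("chr1", 1000L, 1100L, "-")
  trm <- trim_precursor(ivm, pl, flank = 10L, chrom_length = 10000L)
  expect_equal(c(trm$start, trm$end), c(1008L, 1100L))
})

test_that("with no miR*, the span grows toward the predicted opposite arm", {
  iv <- genomic_interval("chr1", 1000L, 1100L, "+")
  pl <- structure(list(mir_interval = c(10L, 32L), mirstar_interval = NULL,
                       mir_arm = "5p"),
                  class = "mature_placement")
  tr <- trim_precursor(iv, pl, flank = 10L, chrom_length = 10000L)
  expect_equal(c(tr$start, tr$end), c(1000L, 1112L))  # miR + 70 + flank 3'-ward
})

test_that("trimming is idempotent once placement is stable", {
  set.seed(13)
  hp <- make_hairpin(34, 7)
  fam <- make_family("famT", hp)
  dna <- gsub("U", "T", hp$sequence, fixed = TRUE)
  genome <- c(chr1 = paste0(strrep("A", 500), dna, strrep("A", 500)))
  region <- genomic_interval("chr1", 480L, 520L + nchar(dna), "+")
  pl1 <- locate_mature(extract_sequence(genome, region), fam)
  t1 <- trim_precursor(region, pl1, 10L, nchar(genome))
  pl2 <- locate_mature(extract_sequence(genome, t1), fam)
  t2 <- trim_precursor(t1, pl2, 10L, nchar(genome))
  expect_equal(t1, t2)
  pl3 <- locate_mature(extract_sequence(genome, t2), fam)
  t3 <- trim_precursor(t2, pl3, 10L, nchar(genome))
  expect_equal(t2, t3)
})

test_that("arm consistency distinguishes valid, loop-overlap and multiloop placements", {
  # canonical stem-loop, matures on opposite arms
  db <- paste0(strrep("(", 25), strrep(".", 6), strrep(")", 25))
  fold <- list(dotbracket = db, mfe = -30)
  pl <- structure(list(mir_interval = c(2L, 24L),
                       mirstar_interval = c(32L, 54L), mir_arm = "5p"),
                  class = "mature_placement")
  expect_equal(check_arm_consistency(pl, fold), "valid")

  # mature centered on the loop
  pl_loop <- structure(list(mir_interval = c(17L, 39L),
                            mirstar_interval = c(40L, 56L), mir_arm = "5p"),
                       class = "mature_placement")
  expect_equal(check_arm_consistency(pl_loop, fold), "loop_overlap")

  # two hairpins under one exterior loop spanned by the matures
  db2 <- paste0("((", strrep("(", 10), strrep(".", 4), strrep(")", 10),
                strrep("(", 10), strrep(".", 4), strrep(")", 10), "))")
  fold2 <- list(dotbracket = db2, mfe = -20)
  pl2 <- structure(list(mir_interval = c(2L, 14L),
                        mirstar_interval = c(36L, 48L), mir_arm = "5p"),
                   class = "mature_placement")
  expect_equal(check_arm_consistency(pl2, fold2), "multiloop")

  # both matures on the 5' arm of one hairpin
  db3 <- paste0(strrep("(", 30), strrep(".", 50), strrep(")", 30))
  pl3 <- structure(list(mir_interval = c(0L, 14L),
                        mirstar_interval = c(15L, 29L), mir_arm = "5p"),
                   class = "mature_placement")
  expect_equal(check_arm_consistency(pl3, list(dotbracket = db3, mfe = -20)),
               "same_arm")

  # small loop overlaps within the tolerance stay valid
  pl4 <- structure(list(mir_interval = c(4L, 26L),   # 1 nt into the loop
                        mirstar_interval = c(32L, 54L), mir_arm = "5p"),
                   class = "mature_placement")
  expect_equal(check_arm_consistency(pl4, fold), "valid")
})
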