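mk_hit <- function(evalue = 1e-10, bitscore = 100, hsp = 50, cov = 1,
                   start = 100L, end = 150L, strand = "+", seqid = "c1",
                   engine = "blast", family = "famX") {
  data.frame(seqid = seqid, start = start, end = end, strand = strand,
             family_id = family, engine = engine, evalue = evalue,
             bitscore = bitscore, hsp_length = hsp, coverage = cov,
             stringsAsFactors = FALSE)
}

test_that("sequence-homology filter keeps exactly the hits inside all three thresholds", {
  h <- rbind(mk_hit(evalue = 0.01, hsp = 20, cov = 0.70),  # all boundaries
             mk_hit(evalue = 0.02, hsp = 100, cov = 1.0),  # E-value out
             mk_hit(evalue = 1e-10, hsp = 19, cov = 1.0),  # HSP out
             mk_hit(evalue = 1e-10, hsp = 100, cov = 0.69))
  kept <- filter_sequence_hits(h)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$evalue, 0.01)
  expect_equal(nrow(filter_sequence_hits(h[0, ])), 0L)
})

test_that("cm filter applies log2(2N) with the gathering-cutoff rescue", {
  N <- 2^31
  co <- family_cutoffs(NULL, N)
  # threshold log2(2*2^31) = 32 exactly
  expect_equal(nrow(filter_cm_hits(mk_hit(bitscore = 33, engine = "cm"), co)), 1L)
  expect_equal(nrow(filter_cm_hits(mk_hit(bitscore = 32, engine = "cm"), co)), 0L)
  # both branches fail: 31.9 < 32 and nBit = 0.319 < 0.32
  co100 <- family_cutoffs(100, N)
  expect_equal(nrow(filter_cm_hits(mk_hit(bitscore = 31.9, engine = "cm"),
                                   co100)), 0L)
  # rescued: nBit = 31.9/90 = 0.354 >= 0.32
  co90 <- family_cutoffs(90, N)
  expect_equal(nrow(filter_cm_hits(mk_hit(bitscore = 31.9, engine = "cm"),
                                   co90)), 1L)
  # rescue never overrides E-value or coverage
  expect_equal(nrow(filter_cm_hits(
    mk_hit(bitscore = 31.9, evalue = 0.5, engine = "cm"), co90)), 0L)
  expect_equal(nrow(filter_cm_hits(
    mk_hit(bitscore = 31.9, cov = 0.5, engine = "cm"), co90)), 0L)
  expect_error(family_cutoffs(-3, N), "positive")
})

test_that("hmm filter applies only the E-value threshold", {
  h <- rbind(mk_hit(evalue = 0.01, cov = NA, hsp = 5, engine = "hmm"),
             mk_hit(evalue = 0.011, cov = 1, engine = "hmm"))
  expect_equal(nrow(filter_hmm_hits(h)), 1L)
})

test_that("filters are idempotent and order-independent", {
  set.seed(11)
  h <- random_hits(40)
  h$evalue <- 10^stats::runif(40, -30, 0)
  h$coverage <- stats::runif(40, 0, 1)
  h$hsp_length <- sample(5:60, 40, replace = TRUE)
  f1 <- filter_sequence_hits(h)
  expect_equal(filter_sequence_hits(f1), f1)
  perm <- sample(nrow(h))
  f2 <- filter_sequence_hits(h[perm, ])
  expect_setequal(rownames(f2), rownames(f1))
})

test_that("overlapping hits merge into extended regions, half-open semantics", {
  h <- rbind(mk_hit(start = 10L, end = 50L), mk_hit(start = 40L, end = 90L))
  r <- merge_hits_to_regions(h)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(10L, 90L))
  expect_equal(nrow(r$hits[[1]]), 2L)

  # abutment is not overlap
  h2 <- rbind(mk_hit(start = 10L, end = 50L), mk_hit(start = 50L, end = 90L))
  expect_equal(nrow(merge_hits_to_regions(h2)), 2L)

  # strands stay separate
  h3 <- rbind(mk_hit(start = 10L, end = 50L, strand = "+"),
              mk_hit(start = 10L, end = 50L, strand = "-"))
  expect_equal(nrow(merge_hits_to_regions(h3)), 2L)
})

test_that("region merging equals the pairwise-merge fixed point and ignores input order", {
  for (seed in 1:10) {
    set.seed(seed)
    h <- random_hits(25)
    r <- merge_hits_to_regions(h)
    expect_equal(r[, c("seqid", "start", "end", "strand")],
                 oracle_merge_intervals(h),
                 ignore_attr = TRUE)
    r2 <- merge_hits_to_regions(h[sample(nrow(h)), ])
    expect_equal(r[, c("seqid", "start", "end", "strand")],
                 r2[, c("seqid", "start", "end", "strand")])
    # every input hit lands in exactly one region's support
    expect_equal(sum(vapply(r$hits, nrow, 0L)), nrow(h))
  }
})

test_that("strand disambiguation follows bitscore, then E-value, then coverage", {
  reg <- function(strand, bit, ev = 1e-10, cov = 0.9) {
    r <- merge_hits_to_regions(mk_hit(strand = strand, bitscore = bit,
                                      evalue = ev, cov = cov))
    r
  }
  # higher bitscore wins
  r <- disambiguate_strands(rbind(reg("+", 50), reg("-", 40)))
  expect_equal(r$status[r$strand == "+"], "candidate")
  expect_equal(r$status[r$strand == "-"], "rejected_strand")
  # equal bitscore: lower E-value wins
  r <- disambiguate_strands(rbind(reg("+", 50, ev = 1e-5),
                                  reg("-", 50, ev = 1e-9)))
  expect_equal(r$status[r$strand == "-"], "candidate")
  expect_equal(r$status[r$strand == "+"], "rejected_strand")
  # full tie: plus kept, warning emitted
  expect_warning(
    r <- disambiguate_strands(rbind(reg("+", 50), reg("-", 50))),
    "tie")
  expect_equal(r$status[r$strand == "+"], "candidate")
  expect_equal(r$status[r$strand == "-"], "rejected_strand")
  # non-overlapping opposite-strand regions are left alone
  r <- disambiguate_strands(rbind(
    merge_hits_to_regions(mk_hit(start = 10L, end = 50L, strand = "+")),
    merge_hits_to_regions(mk_hit(start = 100L, end = 150L, strand = "-"))))
  expect_true(all(r$status == "candidate"))
})

test_that("engine merging unifies same-strand overlaps and keeps singletons", {
  b <- merge_hits_to_regions(mk_hit(start = 100L, end = 180L))
  cm <- merge_hits_to_regions(mk_hit(start = 150L, end = 210L, engine = "cm",
                                     bitscore = 60, evalue = 1e-30, cov = 0.8))
  hm <- merge_hits_to_regions(mk_hit(start = 5000L, end = 5080L,
                                     engine = "hmm", bitscore = 44))
  m <- merge_engines(b, cm, hm)
  expect_equal(nrow(m), 2L)
  joint <- m[m$start == 100L, ]
  expect_equal(joint$end, 210L)
  expect_setequal(joint$hits[[1]]$engine, c("blast", "cm"))
  expect_equal(joint$best_bitscore, 100)   # max
  expect_equal(joint$best_evalue, 1e-30)   # min
  expect_equal(joint$best_coverage, 1)     # max
  expect_equal(m[m$start == 5000L, ]$best_bitscore, 44)
  # disjoint loci: unchanged count
  expect_equal(nrow(merge_engines(b, hm)), 2L)
})

test_that("candidate cap keeps the best bitscores and flags the rest potential", {
  set.seed(5)
  h <- random_hits(60)
  h$start <- seq(1, by = 200, length.out = 60)  # disjoint
  h$end <- h$start + 80L
  regions <- merge_hits_to_regions(h)
  capped <- cap_candidates(regions, limit = 10L)
  expect_equal(nrow(capped$processed), 10L)
  expect_equal(nrow(capped$potential), 50L)
  expect_true(all(capped$potential$status == "potential"))
  expect_true(min(capped$processed$best_bitscore) >=
              max(capped$potential$best_bitscore))
  # under the cap: everything proceeds
  all_in <- cap_candidates(regions, limit = 100L)
  expect_equal(nrow(all_in$processed), 60L)
  expect_equal(nrow(all_in$potential), 0L)
  # boundary ties resolved deterministically
  h$bitscore <- 50; h$evalue <- 1e-10
  regions <- merge_hits_to_regions(h)
  c1 <- cap_candidates(regions, limit = 10L)
  c2 <- cap_candidates(regions[sample(nrow(regions)), ], limit = 10L)
  expect_equal(c1$processed$start, sort(c1$processed$start))
  expect_setequal(c1$processed$start, c2$processed$start)
})

test_that("every hit is conserved across filter, merge, disambiguation and cap", {
  set.seed(21)
  h <- random_hits(80)
  kept <- filter_sequence_hits(h)
  dropped <- nrow(h) - nrow(kept)
  regions <- disambiguate_strands(merge_hits_to_regions(kept))
  capped <- cap_candidates(regions, limit = 5L)
  n_support <- sum(vapply(capped$processed$hits, nrow, 0L)) +
    sum(vapply(capped$potential$hits, nrow, 0L))
  expect_equal(dropped + n_support, nrow(h))
})
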