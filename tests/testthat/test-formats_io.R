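test_that("read_fasta normalizes alphabet, concatenates lines, handles empty input", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGU"), p)
  expect_equal(read_fasta(p), c(x = "ACGT"))
  expect_equal(read_fasta(p, as = "rna"), c(x = "ACGU"))

  writeLines(c(">a desc", "AC", "GT"), p)
  expect_equal(read_fasta(p), c(a = "ACGT"))

  writeLines(character(0), p)
  expect_length(read_fasta(p), 0)

  writeLines(c("ACGT", ">x", "AC"), p)
  expect_error(read_fasta(p), "line 1")

  writeLines(c(">x", "ACGQ"), p)
  expect_error(read_fasta(p), "outside")
})

test_that("fasta round-trips through write_fasta", {
  p <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(one = "ACGTACGTAC", two = "TTTT")
  write_fasta(seqs, p)
  expect_equal(read_fasta(p), seqs)
})

test_that("blast tab6 hits are normalized to 0-based half-open with strand flips", {
  p <- withr::local_tempfile()
  writeLines(c(
    "q1\tchr1\t98.0\t50\t1\t0\t1\t50\t101\t150\t1e-20\t95.2",
    "q1\tchr1\t98.0\t50\t1\t0\t1\t50\t200\t151\t1e-20\t95.2"), p)
  h <- read_tabular_hits(p, "blast-tab6", query_lengths = c(q1 = 50))
  expect_equal(h$start, c(100L, 150L))
  expect_equal(h$end, c(150L, 200L))
  expect_equal(h$strand, c("+", "-"))
  expect_equal(h$engine, c("blast", "blast"))
  expect_equal(h$coverage, c(1, 1))
  expect_equal(h$hsp_length, c(50L, 50L))
  expect_true(all(h$start < h$end))
})

test_that("nhmmer tblout parses with coordinate flip and model coverage", {
  p <- withr::local_tempfile()
  writeLines(c(
    "# comment",
    "chr2 - mir-9 RF0001 1 80 200 151 210 141 1000 - 1.2e-10 55.1 0.2 desc here",
    "#"), p)
  h <- read_tabular_hits(p, "nhmmer-tblout", model_lengths = c("mir-9" = 80))
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 150L)
  expect_equal(h$end, 200L)
  expect_equal(h$strand, "-")
  expect_equal(h$engine, "hmm")
  expect_equal(h$coverage, 1)
  expect_equal(h$evalue, 1.2e-10)
  expect_equal(h$bitscore, 55.1)
})

test_that("cmsearch tblout parses scores and flips minus-strand hits", {
  p <- withr::local_tempfile()
  writeLines(c(
    "#target name accession query ...",
    "chr1 - let-7 RF00027 cm 1 72 5001 5090 + no 1 0.45 0.0 88.3 2.1e-18 ! -",
    "chr1 - let-7 RF00027 cm 1 72 6090 6001 - no 1 0.45 0.0 44.0 1.0e-03 ! -"), p)
  h <- read_tabular_hits(p, "cmsearch-tblout", model_lengths = c("let-7" = 72))
  expect_equal(h$start, c(5000L, 6000L))
  expect_equal(h$end, c(5090L, 6090L))
  expect_equal(h$strand, c("+", "-"))
  expect_equal(h$bitscore, c(88.3, 44.0))
  expect_equal(h$evalue, c(2.1e-18, 1e-3))
  expect_equal(h$coverage, c(1, 1))
})

test_that("tabular parser rejects unknown dialects and bad numeric fields", {
  p <- withr::local_tempfile()
  writeLines("q\ts\t90\txx\t0\t0\t1\t10\t1\t10\t1e-5\t20", p)
  expect_error(read_tabular_hits(p, "psl"), "unknown dialect")
  expect_error(read_tabular_hits(p, "blast-tab6"), "line 1")
  writeLines(c("# only", "# comments"), p)
  expect_equal(nrow(read_tabular_hits(p, "blast-tab6")), 0L)
})

test_that("GFF3 and BED share the documented coordinate conventions", {
  cand <- data.frame(seqid = "chr1", start = 100L, end = 150L, strand = "+",
                     id = "c1", family_id = "mir-1", confidence = "High",
                     status = "accepted", stringsAsFactors = FALSE)
  gff <- withr::local_tempfile(fileext = ".gff3")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_gff3(cand, gff)
  write_bed(cand, bed)
  gline <- grep("^chr1", readLines(gff), value = TRUE)[1]
  gcols <- strsplit(gline, "\t")[[1]]
  expect_equal(as.integer(gcols[4:5]), c(101L, 150L))
  expect_match(gcols[9], "confidence=High")
  bcols <- strsplit(grep("^chr1", readLines(bed), value = TRUE)[1], "\t")[[1]]
  expect_equal(as.integer(bcols[2:3]), c(100L, 150L))
  # bed.start = gff.start - 1, bed.end = gff.end
  expect_equal(as.integer(bcols[2]), as.integer(gcols[4]) - 1L)
  expect_equal(as.integer(bcols[3]), as.integer(gcols[5]))
})

test_that("annotation round-trips through GFF3 on the retained fields", {
  cand <- data.frame(seqid = c("chr1", "chr2"), start = c(0L, 999L),
                     end = c(80L, 1200L), strand = c("+", "-"),
                     id = c("a", "b"), family_id = c("mir-1", "mir-7"),
                     confidence = c("High", "Medium"),
                     status = c("accepted", "accepted"),
                     stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(cand, p)
  back <- read_annotation(p)
  expect_equal(back$start, cand$start)
  expect_equal(back$end, cand$end)
  expect_equal(back$strand, cand$strand)
  expect_equal(back$family, cand$family_id)
  expect_equal(back$confidence, cand$confidence)
})

test_that("writers refuse intervals that exceed the target sequence", {
  cand <- data.frame(seqid = "chr1", start = 100L, end = 150L, strand = "+",
                     id = "oops", family_id = "mir-1", stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".gff3")
  expect_error(write_gff3(cand, p, seq_lengths = c(chr1 = 120)), "oops")
  expect_error(write_bed(cand, p, seq_lengths = c(chr1 = 120)), "oops")
  expect_silent(write_gff3(cand, p, seq_lengths = c(chr1 = 150)))
})

test_that("Stockholm parser handles interleaved blocks and keeps SS_cons", {
  p <- withr::local_tempfile(fileext = ".stk")
  writeLines(c(
    "# STOCKHOLM 1.0",
    "#=GF ID mir-test",
    "#=GS seq1 DE something opaque",
    "seq1 ACGU",
    "seq2 AC-U",
    "#=GC SS_cons <<..",
    "",
    "seq1 ACGU",
    "seq2 ACGU",
    "#=GC SS_cons ..>>",
    "//"), p)
  aln <- read_stockholm(p)
  expect_equal(aln$family_id, "mir-test")
  expect_equal(aln$rows, c(seq1 = "ACGUACGU", seq2 = "AC-UACGU"))
  expect_equal(aln$ss_cons, "((....))")
  expect_true(any(grepl("GS seq1", aln$gf)))
  # round trip
  p2 <- withr::local_tempfile(fileext = ".stk")
  write_stockholm(aln, p2)
  back <- read_stockholm(p2)
  expect_equal(back$rows, aln$rows)
  expect_equal(back$ss_cons, aln$ss_cons)
})

test_that("Stockholm parser rejects unbalanced consensus and ragged rows", {
  p <- withr::local_tempfile(fileext = ".stk")
  writeLines(c("# STOCKHOLM 1.0", "s1 ACGU", "#=GC SS_cons <<.)", "//"), p)
  expect_error(read_stockholm(p), "unbalanced")
  writeLines(c("# STOCKHOLM 1.0", "s1 ACGU", "s2 ACG", "//"), p)
  expect_error(read_stockholm(p), "unequal")
  writeLines(c("just text"), p)
  expect_error(read_stockholm(p), "STOCKHOLM")
})
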