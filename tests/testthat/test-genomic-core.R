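test_that("overlap_fraction uses the smaller-peak denominator", {
  a <- peak_set("chr1", 100, 200, 150, 5, 20)
  b <- peak_set("chr1", 150, 250, 200, 5, 20)
  expect_equal(overlap_fraction(a, b), 0.5)
  expect_equal(overlap_fraction(a, a), 1.0)
  d <- peak_set("chr1", 300, 400, 350, 5, 20)
  expect_equal(overlap_fraction(a, d), 0.0)
  # cross-chromosome pairs are defined as 0
  e <- peak_set("chr2", 100, 200, 150, 5, 20)
  expect_equal(overlap_fraction(a, e), 0.0)
})

test_that("overlap_fraction is symmetric and 1 for nested peaks", {
  set.seed(42)
  for (k in 1:50) {
    s1 <- sample.int(1000, 1); l1 <- sample(10:300, 1)
    s2 <- sample.int(1000, 1); l2 <- sample(10:300, 1)
    a <- peak_set("chr1", s1, s1 + l1, s1, 1, 1)
    b <- peak_set("chr1", s2, s2 + l2, s2, 1, 1)
    expect_equal(overlap_fraction(a, b), overlap_fraction(b, a))
  }
  outer <- peak_set("chr1", 100, 1000, 500, 1, 1)
  inner <- peak_set("chr1", 300, 400, 350, 1, 1)
  expect_equal(overlap_fraction(inner, outer), 1.0)
})

test_that("peak_set enforces its invariants", {
  expect_error(peak_set("chr1", 100, 100, 100, 5, 20), "start >= end")
  expect_error(peak_set("chr1", 100, 200, 250, 5, 20), "summit outside")
  expect_error(peak_set("chr1", 100, 200, 150, -1, 20), "fdr")
  expect_error(peak_set(c("chr1", "chr1"), c(1, 5), c(4, 9), c(2, 6),
                        5, 20, peak_id = c("p", "p")), "unique")
})

test_that("peak I/O round-trips coordinates exactly and handles dialects", {
  ps <- peak_set(c("chr1", "chr1", "chr2"), c(100, 500, 7),
                 c(260, 900, 19), c(180, 650, 11),
                 fdr = c(1.25, 9.99, 15.5), tag_density = c(31.5, 12, 80),
                 label = "io")
  f <- withr::local_tempfile(fileext = ".bed")
  write_peaks(ps, f)
  back <- read_peaks(f, label = "io")
  expect_identical(back$start, ps$start)
  expect_identical(back$end, ps$end)
  expect_identical(back$summit, ps$summit)
  expect_identical(back$fdr, ps$fdr)
  expect_identical(back$tag_density, ps$tag_density)

  # summit offset dialect: start=100, offset=50 -> absolute 150
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrom\tstart\tend\tname\ttag_density\tstrand\tsummit_offset\tfdr_percent",
               "chr1\t100\t200\tp1\t20\t.\t50\t5"), f2)
  expect_equal(read_peaks(f2, "offset")$summit, 150)
  # absolute dialect: the summit column already holds the coordinate
  f2b <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrom\tstart\tend\tname\ttag_density\tstrand\tsummit\tfdr",
               "chr1\t100\t200\tp1\t20\t.\t150\t5"), f2b)
  expect_equal(read_peaks(f2b, "absolute")$summit, 150)

  # malformed rows error with a line number
  f3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrom\tstart\tend\tname\ttag_density\tstrand\tsummit_offset\tfdr_percent",
               "chr1\t100\t100\tp1\t20\t.\t0\t5"), f3)
  expect_error(read_peaks(f3), "line 2")
})

test_that("gene TSS follows strand and bad strands are rejected", {
  g <- gene_set(c("gp", "gm"), "chr1", c("+", "-"),
                c(1000, 1000), c(2000, 2000))
  expect_equal(g$tss[g$gene_id == "gp"], 1000)
  expect_equal(g$tss[g$gene_id == "gm"], 2000)
  expect_equal(g$tes[g$gene_id == "gm"], 1000)
  expect_error(gene_set("g", "chr1", "*", 1, 10), "strand")
})

test_that("read_genes parses GTF (with coordinate shift) and BED12", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", "1001", "1500", ".", "+", ".",
          'gene_id "gA";', sep = "\t"),
    paste("chr1", "src", "five_prime_utr", "1001", "1100", ".", "+", ".",
          'gene_id "gA";', sep = "\t"),
    paste("chr1", "src", "exon", "1801", "2000", ".", "+", ".",
          'gene_id "gA";', sep = "\t"),
    paste("chr2", "src", "exon", "5001", "6000", ".", "-", ".",
          'gene_id "gB";', sep = "\t")), gtf)
  gs <- read_genes(gtf)
  gA <- gs[gs$gene_id == "gA", ]
  expect_equal(gA$start, 1000)  # GTF 1-based -> 0-based
  expect_equal(gA$end, 2000)
  expect_equal(gA$tss, 1000)
  expect_equal(gA$exons[[1]], cbind(c(1000, 1800), c(1500, 2000)))
  expect_equal(gA$utr5[[1]], c(1000, 1100))
  gB <- gs[gs$gene_id == "gB", ]
  expect_equal(gB$tss, 6000)  # minus strand

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chr1", "100", "1000", "tx1", "0", "+", "300", "900",
                   "0", "2", "200,100", "0,800", sep = "\t"), bed)
  bs <- read_genes(bed)
  expect_equal(bs$start, 100)
  expect_equal(bs$exons[[1]], cbind(c(100, 900), c(300, 1000)))
  expect_equal(bs$utr5[[1]], c(100, 300))  # txStart..thickStart on +

  empty <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(), empty)
  expect_warning(gs0 <- read_genes(empty), "no gene")
  expect_equal(nrow(gs0), 0)
})
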