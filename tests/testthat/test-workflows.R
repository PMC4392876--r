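# end-to-end drivers over synthetic fixtures written to disk

write_cistrome_fixture <- function(dir, seed = 29) {
  cfg <- sim_config(seed)
  sim <- simulate_peak_replicates(cfg)
  tg <- simulate_tags(cfg, sim$rep1)
  write_peaks(sim$rep1, file.path(dir, "rep1.bed"))
  write_peaks(sim$rep2, file.path(dir, "rep2.bed"))
  write.table(data.frame(tg$chrom, tg$pos, tg$pos + 1, tg$count),
              file.path(dir, "tags.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  gtf <- file.path(dir, "genes.gtf")
  tss <- seq(50000, by = 100000, length.out = 40)
  writeLines(sprintf(
    "chr1\tsim\texon\t%d\t%d\t.\t+\t.\tgene_id \"G%02d\";",
    tss + 1, tss + 5000, seq_along(tss)), gtf)
  cfg
}

test_that("cistrome workflow writes parseable, provenance-stamped outputs", {
  dir <- withr::local_tempdir()
  write_cistrome_fixture(dir)
  rc <- run_config(rep1 = file.path(dir, "rep1.bed"),
                   rep2 = file.path(dir, "rep2.bed"),
                   genes = file.path(dir, "genes.gtf"),
                   tags = file.path(dir, "tags.bed"),
                   set_b = file.path(dir, "rep2.bed"),
                   out_dir = file.path(dir, "out"), reproducible = TRUE)
  outs <- run_cistrome_workflow(rc, c(chr1 = 5e6, chr2 = 5e6))
  expect_true(all(file.exists(outs)))
  expect_true(all(c("consensus", "annotation", "feature_distribution",
                    "density_matrix", "comparison_counts") %in% names(outs)))
  # every output opens with a provenance header
  for (p in outs)
    expect_match(readLines(p, n = 1), "^# cistromix .*config_md5=.*seed=")
  # outputs parse back
  cons <- read_peaks(outs["consensus"])
  expect_gt(nrow(cons), 0)
  fd <- read.table(outs["feature_distribution"], header = TRUE, sep = "\t",
                   comment.char = "#")
  expect_equal(sum(fd$observed), 1, tolerance = 1e-9)
})

test_that("workflows are deterministic under --reproducible and name failing stages", {
  dir <- withr::local_tempdir()
  write_cistrome_fixture(dir)
  mk <- function(out) run_config(rep1 = file.path(dir, "rep1.bed"),
                                 rep2 = file.path(dir, "rep2.bed"),
                                 genes = file.path(dir, "genes.gtf"),
                                 out_dir = out, reproducible = TRUE)
  o1 <- run_cistrome_workflow(mk(file.path(dir, "o1")), c(chr1 = 5e6, chr2 = 5e6))
  o2 <- run_cistrome_workflow(mk(file.path(dir, "o2")), c(chr1 = 5e6, chr2 = 5e6))
  for (nm in names(o1))
    expect_identical(readLines(o1[[nm]]), readLines(o2[[nm]]))

  bad <- run_config(rep1 = file.path(dir, "nope.bed"),
                    rep2 = file.path(dir, "rep2.bed"),
                    genes = file.path(dir, "genes.gtf"), out_dir = dir)
  expect_error(run_cistrome_workflow(bad, c(chr1 = 5e6)), "nope.bed")
})

test_that("expression workflow chains normalisation through group statistics", {
  dir <- withr::local_tempdir()
  sim <- simulate_expression(sim_config(31, n_normal = 8, n_tumour = 12))
  write_counts(sim$counts, file.path(dir, "counts.csv"))
  write.csv(sim$counts$sample_meta, file.path(dir, "meta.csv"),
            row.names = FALSE)
  rc <- run_config(counts = file.path(dir, "counts.csv"),
                   meta = file.path(dir, "meta.csv"),
                   out_dir = file.path(dir, "out"), reproducible = TRUE)
  outs <- run_expression_workflow(rc)
  expect_true(all(file.exists(outs)))
  expect_true(all(c("normalised", "factors", "correlation", "cluster_orders",
                    "group_stats", "fold_to_normal", "boxplot_summaries")
                  %in% names(outs)))
  corr <- read.table(outs["correlation"], header = TRUE, sep = "\t",
                     comment.char = "#")
  expect_true("FOXM1" %in% corr$gene_id)
  expect_equal(max(corr$r, na.rm = TRUE), 1)  # the anchor itself
  gs <- read.table(outs["group_stats"], header = TRUE, sep = "\t",
                   comment.char = "#")
  expect_lt(gs$p_value[gs$gene_id == "FOXM1"], 0.05)

  # a constant endogenous gene is skipped with a warning, not an abort
  # (lane and reference noise zeroed so normalisation factors stay 1 and the
  # planted flat gene remains flat after scaling)
  sim2 <- simulate_expression(sim_config(31, n_normal = 8, n_tumour = 12,
                                         lane_sd = 0, ref_cv = 0))
  cm <- sim2$counts
  cm$counts <- rbind(cm$counts, FLATGENE = rep(1024, ncol(cm$counts)))
  cm$probe_class <- c(cm$probe_class, FLATGENE = "endogenous")
  write_counts(cm, file.path(dir, "counts2.csv"))
  rc2 <- run_config(counts = file.path(dir, "counts2.csv"),
                    meta = file.path(dir, "meta.csv"),
                    out_dir = file.path(dir, "out2"), reproducible = TRUE)
  expect_warning(outs2 <- run_expression_workflow(rc2), "FLATGENE")
  corr2 <- read.table(outs2[["correlation"]], header = TRUE, sep = "\t",
                      comment.char = "#")
  expect_false("FLATGENE" %in% corr2$gene_id)
})

test_that("run_config rejects unknown keys and round-trips through YAML", {
  expect_error(run_config(bogus = 1), "bogus")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("min_frac: 0.6", "anchor: FOXM1", "seed: 4"), f)
  rc <- read_run_config(f)
  expect_equal(rc$min_frac, 0.6)
  expect_equal(rc$max_fdr, 10)  # defaults preserved
  expect_equal(rc$seed, 4)
})
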