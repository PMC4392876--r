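test_that("generators are pure functions of their config", {
  cfg <- sim_config(99)
  s1 <- simulate_peak_replicates(cfg)
  s2 <- simulate_peak_replicates(cfg)
  expect_identical(s1, s2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_peaks(s1$rep1, f1); write_peaks(s2$rep1, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(simulate_tags(cfg, s1$rep1), simulate_tags(cfg, s1$rep1))
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))
  expect_identical(simulate_knockdown(cfg), simulate_knockdown(cfg))
  # a different seed changes the data
  expect_false(identical(simulate_peak_replicates(sim_config(100)), s1))
})

test_that("consensus finds exactly the planted surviving pairs", {
  for (seed in c(1, 2, 3)) {
    sim <- simulate_peak_replicates(sim_config(seed))
    cons <- replicate_consensus(sim$rep1, sim$rep2)
    expect_equal(cons$n_high_confidence, sum(sim$truth$survives))
    # supporting ids match the planted pairs
    got_pairs <- sort(unname(vapply(cons$support,
                                    function(s) paste(s$rep1[1], s$rep2[1]),
                                    character(1))))
    want <- sim$truth[sim$truth$survives, ]
    expect_equal(got_pairs, sort(paste(want$rep1_id, want$rep2_id)))
  }
})

test_that("all-subthreshold overlap plan yields zero consensus regions", {
  cfg <- sim_config(7, overlap_fracs = 0.49)
  sim <- simulate_peak_replicates(cfg)
  expect_true(all(sim$truth$overlap_frac < 0.5))
  expect_equal(replicate_consensus(sim$rep1, sim$rep2)$n_high_confidence, 0L)
})

test_that("infeasible peak plans are rejected", {
  expect_error(simulate_peak_replicates(
    sim_config(1, n_pairs = 10000, genome = c(chr1 = 1e6))), "infeasible")
})

test_that("tags without background fall inside enrichment envelopes; without enrichment the profile is flat", {
  cfg0 <- sim_config(11, tag_background_rate = 0, tags_per_peak = 100)
  sim <- simulate_peak_replicates(cfg0)
  tg <- simulate_tags(cfg0, sim$rep1)
  near <- vapply(seq_len(nrow(tg)), function(i) {
    any(sim$rep1$chrom == tg$chrom[i] &
          abs(sim$rep1$summit - tg$pos[i]) <= 6 * cfg0$tag_sd)
  }, logical(1))
  expect_true(all(near))

  cfgb <- sim_config(11, tag_background_rate = 0.02, tags_per_peak = 0)
  tgb <- simulate_tags(cfgb, sim$rep1)
  dm <- density_matrix(tgb, sim$rep1)
  prof <- mean_profile(dm)
  # Poisson bound: per-bin expectation rate*bin*npeaks; flat within noise
  expected <- 0.02 * 50
  expect_lt(max(abs(prof - mean(prof))), 5 * sqrt(expected / nrow(dm)))
})

test_that("expression simulator plants recoverable structure", {
  # zero noise: the correlated block tracks the anchor exactly
  cfg0 <- sim_config(13, noise_sd = 0, lane_sd = 0, ref_cv = 0, corr_r = 1,
                     n_corr = 5, n_anti = 0, n_null = 0)
  ex0 <- simulate_expression(cfg0)
  endo0 <- names(ex0$counts$probe_class)[ex0$counts$probe_class == "endogenous"]
  x <- log2(ex0$counts$counts[endo0, ])
  cr <- anchor_correlation(x, "FOXM1")
  blk <- cr$table[grepl("^TGT", cr$table$gene_id), ]
  expect_equal(blk$r, rep(1, 5), tolerance = 1e-6)

  # configured 2:1 tumour/normal anchor medians, zero noise
  cfg1 <- sim_config(13, noise_sd = 0, lane_sd = 0, ref_cv = 0,
                     anchor_log2_effect = 1)
  ex1 <- simulate_expression(cfg1)
  meta <- ex1$counts$sample_meta
  f <- fold_to_normal_median(ex1$counts,
                             meta$sample_id[meta$group == "normal"])
  expect_equal(unname(f["FOXM1", meta$group == "OAC"]),
               rep(2, sum(meta$group == "OAC")))

  expect_error(simulate_expression(sim_config(1, n_normal = 1)), "n_normal")
})

test_that("planted correlation is recovered on average at the cohort size", {
  rs <- vapply(1:60, function(seed) {
    ex <- simulate_expression(sim_config(seed, n_normal = 0, n_tumour = 78,
                                         n_corr = 5, n_anti = 0, n_null = 0))
    nm <- normalise(ex$counts)  # removes the shared lane factor first
    endo <- names(nm$probe_class)[nm$probe_class == "endogenous"]
    cr <- anchor_correlation(log2(nm$counts[endo, ] + 1), "FOXM1")
    mean(cr$table$r[grepl("^TGT", cr$table$gene_id)])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.8), 0.1)
})

test_that("knockdown simulator ground truth drives detection rates", {
  sim <- simulate_knockdown(sim_config(17))
  meta <- sim$counts$sample_meta
  nm <- normalise(sim$counts)
  endo <- names(nm$probe_class)[nm$probe_class == "endogenous"]
  ntc <- meta$sample_id[meta$condition == "siNTC"]
  kd <- meta$sample_id[meta$condition == "siFOXM1"]
  res <- do.call(rbind, lapply(endo, function(g)
    knockdown_test(nm$counts[g, ntc], nm$counts[g, kd], gene_id = g)))
  eff <- sim$truth$gene_id[sim$truth$arm == "siFOXM1" &
                             abs(sim$truth$log2_effect) >= 1]
  # all large planted effects detected
  expect_true(all(res$p_value[res$gene_id %in% eff] < 0.05))
  # planted direction recovered
  expect_true(all(res$log2_fold[res$gene_id %in% eff] < 0))

  # null genes are rarely significant across seeds (~ alpha)
  fp <- 0L; tot <- 0L
  for (seed in 1:15) {
    s <- simulate_knockdown(sim_config(seed))
    m <- s$counts$sample_meta
    nmi <- normalise(s$counts)
    nulls <- setdiff(names(nmi$probe_class)[nmi$probe_class == "endogenous"],
                     s$truth$gene_id[s$truth$arm == "siFOXM1"])
    for (g in nulls) {
      p <- knockdown_test(nmi$counts[g, m$sample_id[m$condition == "siNTC"]],
                          nmi$counts[g, m$sample_id[m$condition == "siFOXM1"]],
                          gene_id = g)$p_value
      tot <- tot + 1L
      if (p < 0.05) fp <- fp + 1L
    }
  }
  expect_lt(fp / tot, 0.2)
})
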