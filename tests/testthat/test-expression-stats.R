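test_that("anchor correlation flags r > threshold strictly and orders samples", {
  m <- rbind(FOXM1 = c(1, 3, 2, 5, 4),
             double = 2 * c(1, 3, 2, 5, 4),
             anti = -c(1, 3, 2, 5, 4),
             mid = c(2, 2, 2, 2, 3))
  colnames(m) <- paste0("s", 1:5)
  cr <- anchor_correlation(m, "FOXM1")
  tab <- cr$table
  expect_equal(tab$r[tab$gene_id == "double"], 1)
  expect_true(tab$passes_threshold[tab$gene_id == "double"])
  expect_equal(tab$r[tab$gene_id == "anti"], -1)
  expect_false(tab$passes_threshold[tab$gene_id == "anti"])
  expect_equal(cr$sample_order, c("s1", "s3", "s2", "s5", "s4"))

  mz <- rbind(m, flat = rep(1, 5))
  expect_warning(crz <- anchor_correlation(mz, "FOXM1"), "flat")
  expect_true(is.na(crz$table$r[crz$table$gene_id == "flat"]))
})

test_that("independent noise at large n gives near-zero correlation", {
  set.seed(41)
  n <- 1000
  m <- rbind(FOXM1 = rnorm(n), noise = rnorm(n))
  colnames(m) <- paste0("s", seq_len(n))
  cr <- anchor_correlation(m, "FOXM1")
  expect_lt(abs(cr$table$r[cr$table$gene_id == "noise"]), 0.1)
})

test_that("hierarchical clustering uses 1 - Pearson with average linkage", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(5, 1, 4, 2))
  colnames(m) <- paste0("s", 1:4)
  hc <- hierarchical_cluster(m, "genes")
  # identical-profile pair merges first at height 0
  first <- hc$hclust$merge[1, ]
  expect_setequal(hc$hclust$labels[-first], c("a", "b"))
  expect_equal(hc$hclust$height[1], 0, tolerance = 1e-12)
  # perfectly anti-correlated pair sits at distance 2
  m2 <- rbind(u = c(1, 2, 3), v = c(3, 2, 1))
  colnames(m2) <- paste0("s", 1:3)
  hc2 <- hierarchical_cluster(m2, "genes")
  expect_equal(max(hc2$hclust$height), 2, tolerance = 1e-12)
  expect_error(hierarchical_cluster(rbind(m, flat = c(1, 1, 1, 1)), "genes"),
               "flat")
})

test_that("Mann-Whitney: exact path, ties path and large-shift detection", {
  r <- mannwhitney(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3)            # exact enumeration, U_A = 0
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$method, "exact")

  same <- mannwhitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)             # tie-corrected approximation
  expect_equal(same$method, "normal_approx")

  set.seed(43)
  a <- rnorm(30); b <- rnorm(30, mean = 3)  # 3-sd shift
  shift <- mannwhitney(a, b)
  expect_lt(shift$p_value, 0.01)
  expect_equal(shift$significance_mark, "**")
  expect_error(mannwhitney(numeric(), 1:3), "empty")
})

test_that("Mann-Whitney null rejection rate is calibrated at the cohort sizes", {
  set.seed(47)
  nrej <- 0L; nsim <- 2000L
  for (i in seq_len(nsim)) {
    p <- mannwhitney(rnorm(24), rnorm(58))$p_value
    if (p < 0.05) nrej <- nrej + 1L
  }
  rate <- nrej / nsim
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("boxplot summary uses interpolated quartiles and strict 1.5 IQR fences", {
  b <- boxplot_summary(c(0, 0, 0, 0, 10))
  expect_equal(b$iqr, 0)
  expect_equal(b$outliers, 10)
  none <- boxplot_summary(c(1, 2, 3, 4, 5, 6))
  expect_equal(length(none$outliers), 0)
  allsame <- boxplot_summary(rep(7, 6))
  expect_equal(allsame$iqr, 0)
  expect_equal(length(allsame$outliers), 0)
  expect_error(boxplot_summary(c(1, 2, 3)), ">= 4")
})

test_that("high/low partition follows the two-criterion rule with strict inequalities", {
  normals <- c(8, 10, 12)  # mean 10, sd 2
  expect_equal(unname(partition_foxm1(21, normals)), "high")  # > 14 and > 20
  expect_equal(unname(partition_foxm1(15, normals)), "low")   # fails 2-fold
  expect_equal(unname(partition_foxm1(20, normals)), "low")   # boundary, strict
  expect_error(partition_foxm1(21, 10), ">= 2")
  # scale invariance: both criteria scale with a positive constant
  set.seed(53)
  for (k in 1:20) {
    nrm <- rlnorm(10); tum <- rlnorm(15, meanlog = 1)
    s <- runif(1, 0.1, 10)
    expect_equal(partition_foxm1(tum, nrm), partition_foxm1(s * tum, s * nrm))
  }
})

test_that("knockdown t-test matches the textbook pooled-variance formula", {
  r <- knockdown_test(c(10, 12, 14), c(4, 6, 8))
  expect_equal(unname(r$statistic), 3.674, tolerance = 1e-3)
  expect_equal(unname(r$df), 4)
  expect_equal(r$p_value, 0.0213, tolerance = 1e-2)
  expect_equal(r$fold_change, 0.5)
  expect_equal(r$log2_fold, -1)

  same <- knockdown_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$fold_change, 1)

  expect_error(knockdown_test(c(2, 2, 2), c(4, 4, 4)), "zero pooled variance")

  set.seed(59)
  for (k in 1:50) {
    x <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2))
    got <- knockdown_test(x, y)
    want <- oracle_pooled_t(x, y)
    expect_equal(unname(got$statistic), want$t, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
})

test_that("Venn overlap partitions genes and flags discordant directions", {
  a <- data.frame(gene_id = c("a", "b", "c"), direction = c(1, 1, -1))
  b <- data.frame(gene_id = c("b", "c", "d"), direction = c("up", "up", "down"))
  v <- venn_overlap(a, b)
  expect_setequal(v$shared, c("b", "c"))
  expect_equal(v$discordant, "c")
  expect_equal(unname(v$counts), c(1, 1, 2))
  v2 <- venn_overlap(a, data.frame(gene_id = "z", direction = 1))
  expect_equal(length(v2$shared), 0)
  v3 <- venn_overlap(a, a)
  expect_equal(length(v3$discordant), 0)
  expect_setequal(v3$shared, a$gene_id)
})

test_that("group_stats runs gene-wise and skips constant genes", {
  set.seed(61)
  m <- rbind(up = c(rnorm(5, 0), rnorm(5, 3)),
             flat = rep(2, 10),
             ns = rnorm(10))
  colnames(m) <- paste0("s", 1:10)
  expect_warning(gs <- group_stats(m, paste0("s", 1:5), paste0("s", 6:10),
                                   "normal", "OAC"), "flat")
  expect_setequal(gs$gene_id, c("up", "ns"))
  expect_lt(gs$p_value[gs$gene_id == "up"], 0.05)
})
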