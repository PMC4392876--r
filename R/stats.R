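#' Rank genes by Pearson correlation with an anchor gene
#'
#' Computes each gene's Pearson correlation with the anchor gene (e.g. FOXM1)
#' across samples and flags genes exceeding the threshold (strictly).
#' Also returns the sample ordering by ascending anchor expression, the order
#' used to display correlation heatmaps.
#'
#' @param m a `CountMatrix`/`NormalisedMatrix` or plain genes x samples matrix.
#' @param anchor gene id of the anchor.
#' @param threshold correlation threshold, strict. Default 0.7.
#' @param genes optional subset of gene ids to test.
#' @return an object of class `CorrelationResult`: list with `table` (data
#'   frame `gene_id`, `r`, `passes_threshold`; `r` is `NA` for zero-variance
#'   genes, with a warning), `sample_order` (sample ids by ascending anchor
#'   expression), `anchor`, `threshold`.
#' @export
anchor_correlation <- function(m, anchor, threshold = 0.7, genes = NULL) {
  x <- expression_values(m, genes)
  if (!anchor %in% rownames(x)) {
    xa <- expression_values(m, anchor)
    x <- rbind(x, xa)
  }
  if (ncol(x) < 3) stop("need at least 3 samples")
  a <- x[anchor, ]
  if (stats::sd(a) == 0) stop("anchor gene has zero variance")
  sds <- apply(x, 1, stats::sd)
  r <- rep(NA_real_, nrow(x))
  ok <- sds > 0
  r[ok] <- as.numeric(stats::cor(t(x[ok, , drop = FALSE]), a))
  if (any(!ok))
    warning("zero-variance gene(s), correlation undefined: ",
            paste(rownames(x)[!ok], collapse = ", "))
  tab <- data.frame(gene_id = rownames(x), r = r,
                    passes_threshold = !is.na(r) & r > threshold,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$r, tab$gene_id, na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 sample_order = colnames(x)[order(a, colnames(x))],
                 anchor = anchor, threshold = threshold),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("CorrelationResult vs '%s': %d/%d genes with r > %g\n",
              x$anchor, sum(x$table$passes_threshold), nrow(x$table),
              x$threshold))
  print.data.frame(utils::head(x$table, 10))
  invisible(x)
}

#' Unsupervised hierarchical clustering on correlation distance
#'
#' Agglomerative clustering of genes (rows) or samples (columns) with
#' distance `1 - Pearson r` and average linkage — the defaults of classic
#' microarray viewers. Items with zero variance have no defined correlation
#' and are rejected.
#'
#' @param m a `CountMatrix` or plain matrix (genes x samples); typically
#'   z-scored first.
#' @param axis `"genes"` (rows) or `"samples"` (columns).
#' @param genes optional subset of gene ids.
#' @return list with `hclust` (the [stats::hclust()] tree) and `order`
#'   (leaf ids, left to right).
#' @export
hierarchical_cluster <- function(m, axis = c("genes", "samples"),
                                 genes = NULL) {
  axis <- match.arg(axis)
  x <- expression_values(m, genes)
  if (axis == "samples") x <- t(x)
  if (nrow(x) < 2) stop("need at least 2 items to cluster")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance item(s): ", paste(rownames(x)[sds == 0],
                                          collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(t(x)))
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, order = rownames(x)[hc$order])
}

# significance marks at the conventional cutoffs
sig_mark <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Mann-Whitney U test between two sample groups
#'
#' Two-sided rank-sum comparison of a gene's expression between two groups of
#' tissue samples. Uses the exact U distribution when `n_a + n_b <= 12` and
#' there are no ties, and the normal approximation with tie and continuity
#' correction otherwise. Fold change is the ratio of group medians
#' (`b` relative to `a`, the reference group).
#'
#' @param values_a,values_b numeric vectors, both non-empty.
#' @param group_a_label,group_b_label labels for reporting.
#' @param gene_id optional gene id carried through.
#' @return an object of class `GroupComparison`: one-row data frame with
#'   `gene_id`, `group_a_label`, `group_b_label`, `n_a`, `n_b`, `statistic`
#'   (U of group a), `p_value`, `significance_mark`, `fold_change`.
#' @examples
#' mannwhitney(c(1, 2), c(3, 4))  # exact two-sided p = 1/3
#' @export
mannwhitney <- function(values_a, values_b, group_a_label = "a",
                        group_b_label = "b", gene_id = NA_character_) {
  if (!length(values_a) || !length(values_b)) stop("empty group")
  n <- length(values_a) + length(values_b)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- n <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  med_a <- stats::median(values_a); med_b <- stats::median(values_b)
  fold <- if (med_a > 0) med_b / med_a else NA_real_
  structure(data.frame(gene_id = gene_id,
                       group_a_label = group_a_label,
                       group_b_label = group_b_label,
                       n_a = length(values_a), n_b = length(values_b),
                       statistic = unname(wt$statistic),
                       p_value = min(1, wt$p.value),
                       significance_mark = sig_mark(wt$p.value),
                       fold_change = fold,
                       method = if (exact) "exact" else "normal_approx",
                       stringsAsFactors = FALSE),
            class = c("GroupComparison", "data.frame"))
}

#' Boxplot five-number summary with 1.5 IQR outlier rule
#'
#' Quartiles by linear interpolation of order statistics
#' ([stats::quantile()] type 7); outliers are values strictly beyond
#' `q3 + 1.5*IQR` or `q1 - 1.5*IQR`.
#'
#' @param values numeric vector with at least 4 values.
#' @param gene_id,group optional labels carried through.
#' @return an object of class `BoxplotSummary`: list with `q1`, `median`,
#'   `q3`, `iqr`, `whisker_lo`, `whisker_hi`, `outliers`, `n`, labels.
#' @export
boxplot_summary <- function(values, gene_id = NA_character_,
                            group = NA_character_) {
  if (length(values) < 4) stop("boxplot summary needs >= 4 values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
  out <- values[values < lo | values > hi]
  inside <- values[values >= lo & values <= hi]
  structure(list(gene_id = gene_id, group = group,
                 q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
                 whisker_lo = min(inside), whisker_hi = max(inside),
                 outliers = sort(out), n = length(values)),
            class = "BoxplotSummary")
}

#' @export
print.BoxplotSummary <- function(x, ...) {
  cat(sprintf("BoxplotSummary (n=%d): q1=%g median=%g q3=%g, %d outlier(s)\n",
              x$n, x$q1, x$median, x$q3, length(x$outliers)))
  invisible(x)
}

#' Partition tumour samples into high / low anchor expression
#'
#' A tumour sample is labelled `high` when its value is strictly greater than
#' both `mean(normals) + 2*sd(normals)` (sample sd, n-1 denominator) and
#' `2 * mean(normals)`; otherwise `low`.
#'
#' @param tumour_values numeric vector of tumour-sample expression.
#' @param normal_values numeric vector, >= 2 normal samples.
#' @return character vector of labels (`"high"`/`"low"`), named like
#'   `tumour_values`.
#' @examples
#' partition_foxm1(c(21, 15), c(8, 10, 12))  # "high" "low"
#' @export
partition_foxm1 <- function(tumour_values, normal_values) {
  if (length(normal_values) < 2) stop("need >= 2 normal values")
  mu <- mean(normal_values); s <- stats::sd(normal_values)
  high <- tumour_values > mu + 2 * s & tumour_values > 2 * mu
  stats::setNames(ifelse(high, "high", "low"), names(tumour_values))
}

#' Knockdown effect test (pooled-variance two-sample t)
#'
#' Unpaired two-tailed Student's t test with equal variance assumed, control
#' versus siRNA-treated replicates. Fold change is `mean(treated) /
#' mean(control)` with the control taken as 1; `log2_fold` is its log2, the
#' scale used for knockdown heatmaps.
#'
#' @param control_replicates,treated_replicates numeric vectors, >= 2 each.
#' @param gene_id optional gene id carried through.
#' @param control_label,treated_label labels for reporting.
#' @return a `GroupComparison` one-row data frame with `statistic` (t),
#'   `df`, `p_value`, `significance_mark`, `fold_change`, `log2_fold`.
#' @examples
#' knockdown_test(c(10, 12, 14), c(4, 6, 8))  # t = 3.674, p ~ 0.021, fold 0.5
#' @export
knockdown_test <- function(control_replicates, treated_replicates,
                           gene_id = NA_character_,
                           control_label = "siNTC",
                           treated_label = "treated") {
  if (length(control_replicates) < 2 || length(treated_replicates) < 2)
    stop("need >= 2 replicates per arm")
  if (stats::sd(control_replicates) == 0 &&
      stats::sd(treated_replicates) == 0)
    stop("zero pooled variance: both arms are constant")
  tt <- stats::t.test(control_replicates, treated_replicates,
                      var.equal = TRUE)
  mc <- mean(control_replicates); mt <- mean(treated_replicates)
  fold <- if (mc != 0) mt / mc else NA_real_
  structure(data.frame(gene_id = gene_id,
                       group_a_label = control_label,
                       group_b_label = treated_label,
                       n_a = length(control_replicates),
                       n_b = length(treated_replicates),
                       statistic = unname(tt$statistic),
                       df = unname(tt$parameter),
                       p_value = tt$p.value,
                       significance_mark = sig_mark(tt$p.value),
                       fold_change = fold,
                       log2_fold = if (!is.na(fold) && fold > 0) log2(fold)
                                   else NA_real_,
                       stringsAsFactors = FALSE),
            class = c("GroupComparison", "data.frame"))
}

#' Two-way Venn partition of significant genes with direction concordance
#'
#' Partitions two sets of significant genes (e.g. from two different
#' knockdowns) into exclusive and shared groups, and flags shared genes whose
#' direction of change disagrees between the two sets.
#'
#' @param set_a,set_b data frames with columns `gene_id` and `direction`
#'   (positive/negative number, or `"up"`/`"down"`).
#' @return list with `a_only`, `b_only`, `shared` (gene id vectors), `counts`,
#'   and `discordant` (shared genes with opposite directions).
#' @export
venn_overlap <- function(set_a, set_b) {
  norm_dir <- function(d) {
    if (is.character(d)) ifelse(tolower(d) %in% c("up", "+"), 1, -1)
    else sign(as.numeric(d))
  }
  a <- stats::setNames(norm_dir(set_a$direction), set_a$gene_id)
  b <- stats::setNames(norm_dir(set_b$direction), set_b$gene_id)
  shared <- sort(intersect(names(a), names(b)))
  disc <- shared[a[shared] != b[shared]]
  list(a_only = sort(setdiff(names(a), names(b))),
       b_only = sort(setdiff(names(b), names(a))),
       shared = shared,
       discordant = disc,
       counts = c(a_only = length(setdiff(names(a), names(b))),
                  b_only = length(setdiff(names(b), names(a))),
                  shared = length(shared)))
}

#' Per-gene group comparison across an expression matrix
#'
#' Applies [mannwhitney()] gene-by-gene for a two-group contrast defined by
#' sample metadata, e.g. normal vs tumour or early vs late stage. Genes whose
#' values are constant across all samples are skipped with a warning.
#'
#' @param m a `CountMatrix`/`NormalisedMatrix` or plain matrix.
#' @param group_a_ids,group_b_ids sample ids of the two groups (group a is
#'   the reference for fold changes).
#' @param group_a_label,group_b_label labels for reporting.
#' @param genes optional subset of gene ids.
#' @return data frame of one [mannwhitney()] row per tested gene.
#' @export
group_stats <- function(m, group_a_ids, group_b_ids,
                        group_a_label = "a", group_b_label = "b",
                        genes = NULL) {
  x <- expression_values(m, genes)
  miss <- setdiff(c(group_a_ids, group_b_ids), colnames(x))
  if (length(miss))
    stop("sample(s) not in matrix: ", paste(miss, collapse = ", "))
  res <- lapply(rownames(x), function(g) {
    va <- x[g, group_a_ids]; vb <- x[g, group_b_ids]
    if (stats::sd(c(va, vb)) == 0) return(NULL)
    mannwhitney(va, vb, group_a_label, group_b_label, gene_id = g)
  })
  skipped <- rownames(x)[vapply(res, is.null, logical(1))]
  if (length(skipped))
    warning("constant gene(s) skipped: ", paste(skipped, collapse = ", "))
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
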