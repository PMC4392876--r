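#' Construct a probes-by-samples count matrix
#'
#' The container for NanoString nCounter-style digital counts: a non-negative
#' probes x samples matrix, a probe class per probe (`endogenous`,
#' `positive_control` or `reference`) and a sample-metadata table (tissue
#' group, stage, siRNA condition, ...).
#'
#' @param counts numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids); counts >= 0.
#' @param probe_class character vector (length nrow) of probe classes.
#' @param sample_meta optional data frame keyed by `sample_id` (or with
#'   rownames matching colnames of `counts`).
#' @return an object of class `CountMatrix`: list with `counts`,
#'   `probe_class`, `sample_meta`.
#' @export
count_matrix <- function(counts, probe_class,
                         sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("probe ids must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  probe_class <- as.character(probe_class)
  stopifnot(length(probe_class) == nrow(counts))
  ok <- c("endogenous", "positive_control", "reference")
  if (!all(probe_class %in% ok))
    stop("probe_class must be one of: ", paste(ok, collapse = ", "))
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = colnames(counts),
                              stringsAsFactors = FALSE)
  } else {
    if (is.null(sample_meta$sample_id))
      sample_meta$sample_id <- rownames(sample_meta)
    sample_meta <- sample_meta[match(colnames(counts),
                                     sample_meta$sample_id), , drop = FALSE]
    if (anyNA(sample_meta$sample_id))
      stop("sample_meta missing rows for some samples")
    rownames(sample_meta) <- NULL
  }
  structure(list(counts = counts,
                 probe_class = stats::setNames(probe_class, rownames(counts)),
                 sample_meta = sample_meta),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d probes x %d samples (%d endogenous, %d positive control, %d reference)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$probe_class == "endogenous"),
              sum(x$probe_class == "positive_control"),
              sum(x$probe_class == "reference")))
  invisible(x)
}

#' Read a count matrix from CSV
#'
#' Expects columns `probe_id`, `probe_class`, then one column per sample.
#'
#' @param path counts CSV path.
#' @param meta_path optional sample-metadata CSV keyed by `sample_id`.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, meta_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("probe_id", "probe_class") %in% names(df)))
    stop("counts CSV needs probe_id and probe_class columns")
  m <- as.matrix(df[, setdiff(names(df), c("probe_id", "probe_class")),
                    drop = FALSE])
  rownames(m) <- df$probe_id
  meta <- if (!is.null(meta_path))
    utils::read.csv(meta_path, stringsAsFactors = FALSE) else NULL
  count_matrix(m, df$probe_class, meta)
}

#' Write a count matrix to CSV
#' @param x a `CountMatrix` (or `NormalisedMatrix`).
#' @param path output path.
#' @param header_lines optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, header_lines = NULL) {
  df <- data.frame(probe_id = rownames(x$counts),
                   probe_class = unname(x$probe_class),
                   x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Geometric mean
#'
#' `exp(mean(log(x)))` of strictly positive values. Zeros must be floored
#' before calling (see [normalise()]).
#'
#' @param values positive numeric vector.
#' @return the geometric mean.
#' @examples geometric_mean(c(2, 8))  # 4
#' @export
geometric_mean <- function(values) {
  if (!length(values)) stop("geometric mean of empty input")
  if (any(values <= 0)) stop("geometric mean requires positive values")
  exp(mean(log(values)))
}

# geometric mean per column with zero-flooring to 1 (warns once)
floored_col_geomeans <- function(m, what) {
  if (any(m == 0)) {
    warning(sprintf("%d zero %s count(s) floored to 1 for geometric mean",
                    sum(m == 0), what))
    m[m == 0] <- 1
  }
  if (any(m < 0)) stop("negative counts")
  apply(m, 2, geometric_mean)
}

#' Two-stage NanoString-style count normalisation
#'
#' Stage 1 (positive controls): each sample is scaled by
#' `mean(geomean_pc) / geomean_pc[sample]`, where `geomean_pc` is the
#' geometric mean of the positive-control spike-in probes in that sample and
#' the numerator is the arithmetic mean of those geometric means across
#' samples. Stage 2 (reference genes) applies the same formula to the chosen
#' reference probes on the stage-1 output; the stage-2 factor rescales the
#' assay content (endogenous and reference probes) while spike-in controls
#' keep their stage-1 values, which makes the whole operation idempotent.
#' Zero counts entering a geometric mean are floored to 1 with a warning;
#' endogenous zeros are untouched.
#'
#' @param counts a [count_matrix()] with at least one positive-control and one
#'   reference probe.
#' @param ref_probe_ids reference probe ids (e.g. `c("ALAS1","GAPDH","HMBS")`
#'   for cell lines, or the five-gene clinical set); defaults to all probes of
#'   class `reference`.
#' @return an object of class `NormalisedMatrix` (also a `CountMatrix`):
#'   the scaled matrix plus per-sample `pc_factor` and `ref_factor`.
#' @export
normalise <- function(counts, ref_probe_ids = NULL) {
  stopifnot(inherits(counts, "CountMatrix"))
  pc <- names(counts$probe_class)[counts$probe_class == "positive_control"]
  if (!length(pc)) stop("no positive-control probes")
  if (is.null(ref_probe_ids))
    ref_probe_ids <- names(counts$probe_class)[counts$probe_class == "reference"]
  miss <- setdiff(ref_probe_ids, rownames(counts$counts))
  if (length(miss))
    stop("reference probe(s) not in matrix: ", paste(miss, collapse = ", "))
  if (!length(ref_probe_ids)) stop("no reference probes")

  gm_pc <- floored_col_geomeans(counts$counts[pc, , drop = FALSE],
                                "positive-control")
  pc_factor <- mean(gm_pc) / gm_pc
  stage1 <- sweep(counts$counts, 2, pc_factor, `*`)

  gm_ref <- floored_col_geomeans(stage1[ref_probe_ids, , drop = FALSE],
                                 "reference")
  if (any(gm_ref == 0))
    stop("zero reference geometric mean in sample(s): ",
         paste(colnames(stage1)[gm_ref == 0], collapse = ", "))
  ref_factor <- mean(gm_ref) / gm_ref
  # the reference-gene factor rescales assay content (endogenous + reference
  # probes); spike-in controls keep their stage-1 values, so a repeat pass
  # finds both probe classes already on target and returns unit factors
  out <- sweep(stage1, 2, ref_factor, `*`)
  out[pc, ] <- stage1[pc, ]

  structure(list(counts = out, probe_class = counts$probe_class,
                 sample_meta = counts$sample_meta,
                 pc_factor = pc_factor, ref_factor = ref_factor,
                 ref_probe_ids = ref_probe_ids),
            class = c("NormalisedMatrix", "CountMatrix"))
}

#' @export
print.NormalisedMatrix <- function(x, ...) {
  NextMethod()
  cat(sprintf("  normalised (pc factors %.3g-%.3g, ref factors %.3g-%.3g)\n",
              min(x$pc_factor), max(x$pc_factor),
              min(x$ref_factor), max(x$ref_factor)))
  invisible(x)
}

#' Per-gene z-scores across samples
#'
#' Centres and scales each endogenous gene across all samples:
#' `(x - mean) / sd` with the sample standard deviation (n-1 denominator),
#' the representation used in expression heatmaps.
#'
#' @param m a `CountMatrix` / `NormalisedMatrix`, or a plain numeric matrix
#'   (genes x samples).
#' @param genes optional subset of gene ids (default: endogenous probes, or
#'   all rows for a plain matrix).
#' @return numeric matrix of z-scores, same orientation.
#' @export
zscore_by_gene <- function(m, genes = NULL) {
  x <- expression_values(m, genes)
  if (ncol(x) < 2) stop("z-scores need at least 2 samples")
  sds <- apply(x, 1, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero))
    stop("zero-variance gene(s): ",
         paste(rownames(x)[zero], collapse = ", "))
  (x - rowMeans(x)) / sds
}

#' Expression relative to the median of the normal samples
#'
#' Divides each gene's values by that gene's median across the normal-tissue
#' samples, so the normal median maps to 1 — the scale used for
#' tumour-vs-normal boxplots.
#'
#' @param m as in [zscore_by_gene()].
#' @param normal_sample_ids column ids of the normal samples.
#' @param genes optional subset of gene ids.
#' @return matrix of fold changes relative to the normal median.
#' @export
fold_to_normal_median <- function(m, normal_sample_ids, genes = NULL) {
  x <- expression_values(m, genes)
  miss <- setdiff(normal_sample_ids, colnames(x))
  if (length(miss))
    stop("normal sample(s) not in matrix: ", paste(miss, collapse = ", "))
  if (!length(normal_sample_ids)) stop("need at least one normal sample")
  med <- apply(x[, normal_sample_ids, drop = FALSE], 1, stats::median)
  if (any(med <= 0))
    stop("non-positive normal median for gene(s): ",
         paste(rownames(x)[med <= 0], collapse = ", "))
  x / med
}

# matrix view: endogenous rows of a CountMatrix, or a plain matrix as-is
expression_values <- function(m, genes = NULL) {
  if (inherits(m, "CountMatrix")) {
    x <- m$counts
    if (is.null(genes))
      genes <- names(m$probe_class)[m$probe_class == "endogenous"]
  } else {
    x <- as.matrix(m)
    if (is.null(genes)) genes <- rownames(x)
  }
  miss <- setdiff(genes, rownames(x))
  if (length(miss)) stop("gene(s) not in matrix: ", paste(miss, collapse = ", "))
  x[genes, , drop = FALSE]
}
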