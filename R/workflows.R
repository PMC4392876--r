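#' Build a workflow run configuration
#'
#' Flat key-value configuration shared by the two workflow drivers and the
#' command-line wrapper. Defaults are the standard analysis thresholds:
#' 50% smaller-peak overlap, FDR < 10, TD > 15 (consensus) / 30
#' (high-sensitivity pooled filter), 5 kb upstream / 1 kb downstream TSS
#' windows with a 1 kb promoter pad, 5 kb flank / 50 bp density bins,
#' correlation threshold 0.7 and significance marks at 0.05 / 0.01.
#'
#' @param ... named overrides of the defaults; unknown keys are rejected.
#' @return a list of class `RunConfig`.
#' @export
run_config <- function(...) {
  cfg <- list(min_frac = 0.5, max_fdr = 10, min_td = 15, min_td_pooled = 30,
              upstream = 5000, downstream = 1000, promoter_pad = 1000,
              flank = 5000, bin_size = 50, corr_threshold = 0.7,
              alpha = 0.05, alpha_strong = 0.01,
              anchor = "FOXM1", seed = 1L, reproducible = FALSE,
              rep1 = NULL, rep2 = NULL, set_b = NULL, genes = NULL,
              tags = NULL, counts = NULL, meta = NULL,
              ref_probes = NULL, normal_group = "normal",
              tumour_group = "OAC", out_dir = ".")
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = c("RunConfig", "list"))
}

#' Read a RunConfig from a flat YAML file
#' @param path YAML file of scalar key-value pairs.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# provenance header lines stamped into every workflow output
provenance_header <- function(cfg) {
  tmp <- tempfile(); on.exit(unlink(tmp))
  # hash the analysis parameters and inputs, not where results are written
  keys <- setdiff(names(cfg), c("reproducible", "out_dir"))
  writeLines(yaml::as.yaml(cfg[order(names(cfg))][keys]), tmp)
  hash <- unname(tools::md5sum(tmp))
  ver <- as.character(utils::packageVersion("cistromix"))
  lines <- sprintf("# cistromix %s | config_md5=%s | seed=%s",
                   ver, hash, cfg$seed)
  if (!isTRUE(cfg$reproducible))
    lines <- c(lines, sprintf("# run_at=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  lines
}

write_tsv <- function(df, path, header_lines = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("workflow stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the cistrome workflow
#'
#' Chains replicate consensus, optional cross-cell-type comparison, nearest
#' gene annotation, genomic feature distribution and summit-centred
#' tag-density profiling, writing one delimited output per stage, each with a
#' provenance header (tool version, config hash, seed).
#'
#' @param cfg a [run_config()] with at least `rep1`, `rep2`, `genes` and
#'   `out_dir` set; `set_b` and `tags` stages run when those inputs are given.
#' @param genome_lengths named chromosome lengths for the feature
#'   distribution.
#' @return named character vector of output paths, invisibly.
#' @export
run_cistrome_workflow <- function(cfg, genome_lengths) {
  stopifnot(inherits(cfg, "RunConfig"))
  for (key in c("rep1", "rep2", "genes")) {
    if (is.null(cfg[[key]])) stop("missing required input: ", key)
    if (!file.exists(cfg[[key]])) stop("input file not found: ", cfg[[key]],
                                       " (", key, ")")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(cfg)
  outs <- character()

  rep1 <- stage("read_rep1", read_peaks(cfg$rep1))
  rep2 <- stage("read_rep2", read_peaks(cfg$rep2))
  genes <- stage("read_genes", read_genes(cfg$genes))

  cons <- stage("consensus",
                replicate_consensus(rep1, rep2, cfg$min_frac, cfg$max_fdr,
                                    cfg$min_td))
  p <- file.path(cfg$out_dir, "consensus.bed")
  write_peaks(cons$regions, p, hdr); outs["consensus"] <- p

  if (!is.null(cfg$set_b)) {
    if (!file.exists(cfg$set_b)) stop("input file not found: ", cfg$set_b)
    b <- stage("read_set_b", read_peaks(cfg$set_b))
    cmpr <- stage("compare", compare_peak_sets(cons$regions, b, cfg$min_frac))
    for (nm in c("shared_a", "unique_a", "shared_b", "unique_b")) {
      p <- file.path(cfg$out_dir, paste0(nm, ".bed"))
      write_peaks(cmpr[[nm]], p, hdr); outs[nm] <- p
    }
    p <- file.path(cfg$out_dir, "comparison_counts.tsv")
    write_tsv(data.frame(class = names(cmpr$counts),
                         n = unname(cmpr$counts)), p, hdr)
    outs["comparison_counts"] <- p
  }

  ann <- stage("annotate",
               assign_nearest_gene(cons$regions, genes, cfg$upstream,
                                   cfg$downstream, cfg$promoter_pad))
  p <- file.path(cfg$out_dir, "annotation.tsv")
  write_tsv(ann, p, hdr); outs["annotation"] <- p

  fd <- stage("distribution",
              feature_distribution(cons$regions, genes, genome_lengths))
  p <- file.path(cfg$out_dir, "feature_distribution.tsv")
  write_tsv(data.frame(class = names(fd$observed_fraction),
                       observed = unname(fd$observed_fraction),
                       background = unname(fd$background_fraction)), p, hdr)
  outs["feature_distribution"] <- p

  if (!is.null(cfg$tags)) {
    if (!file.exists(cfg$tags)) stop("input file not found: ", cfg$tags)
    tg <- stage("read_tags", read_tags(cfg$tags))
    dm <- stage("density",
                density_matrix(tg, cons$regions, cfg$flank, cfg$bin_size))
    p <- file.path(cfg$out_dir, "density_matrix.tsv")
    write_tsv(data.frame(peak_id = rownames(dm),
                         as.data.frame(unclass(dm)[, , drop = FALSE]),
                         check.names = FALSE), p, hdr)
    outs["density_matrix"] <- p
    p <- file.path(cfg$out_dir, "mean_profile.tsv")
    mp <- mean_profile(dm)
    write_tsv(data.frame(offset = as.numeric(names(mp)),
                         mean_tags = unname(mp)), p, hdr)
    outs["mean_profile"] <- p
  }
  invisible(outs)
}

#' Run the expression workflow
#'
#' Chains two-stage normalisation, anchor-gene correlation ranking,
#' z-scoring, hierarchical clustering of genes and samples, tumour-vs-normal
#' group statistics, fold-to-normal-median transforms and per-group boxplot
#' summaries, writing one delimited output per stage with provenance headers.
#' Genes that are constant across samples are skipped with a warning rather
#' than aborting.
#'
#' @param cfg a [run_config()] with `counts` (and optionally `meta`,
#'   `ref_probes`, `anchor`, group labels) set.
#' @return named character vector of output paths, invisibly.
#' @export
run_expression_workflow <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (is.null(cfg$counts)) stop("missing required input: counts")
  if (!file.exists(cfg$counts)) stop("input file not found: ", cfg$counts)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(cfg)
  outs <- character()

  cm <- stage("read_counts", read_counts(cfg$counts, cfg$meta))
  nm <- stage("normalise", normalise(cm, cfg$ref_probes))
  p <- file.path(cfg$out_dir, "normalised.csv")
  write_counts(nm, p, hdr); outs["normalised"] <- p
  p <- file.path(cfg$out_dir, "factors.tsv")
  write_tsv(data.frame(sample_id = colnames(nm$counts),
                       pc_factor = unname(nm$pc_factor),
                       ref_factor = unname(nm$ref_factor)), p, hdr)
  outs["factors"] <- p

  endo <- names(nm$probe_class)[nm$probe_class == "endogenous"]
  x <- log2(nm$counts[endo, , drop = FALSE] + 1)
  constant <- apply(x, 1, stats::sd) == 0
  if (any(constant)) {
    warning("constant gene(s) skipped: ",
            paste(endo[constant], collapse = ", "))
    x <- x[!constant, , drop = FALSE]
  }

  cr <- stage("correlate",
              anchor_correlation(x, cfg$anchor, cfg$corr_threshold))
  p <- file.path(cfg$out_dir, "correlation.tsv")
  write_tsv(cr$table, p, hdr); outs["correlation"] <- p

  z <- stage("zscore", zscore_by_gene(x))
  gclust <- stage("cluster_genes", hierarchical_cluster(z, "genes"))
  sclust <- stage("cluster_samples", hierarchical_cluster(z, "samples"))
  p <- file.path(cfg$out_dir, "cluster_orders.tsv")
  write_tsv(data.frame(axis = rep(c("genes", "samples"),
                                  c(length(gclust$order),
                                    length(sclust$order))),
                       position = c(seq_along(gclust$order),
                                    seq_along(sclust$order)),
                       id = c(gclust$order, sclust$order)), p, hdr)
  outs["cluster_orders"] <- p

  meta <- nm$sample_meta
  if (!is.null(meta$group) &&
      all(c(cfg$normal_group, cfg$tumour_group) %in% meta$group)) {
    normals <- meta$sample_id[meta$group == cfg$normal_group]
    tumours <- meta$sample_id[meta$group == cfg$tumour_group]
    gs <- stage("groupstats",
                suppressWarnings(group_stats(x, normals, tumours,
                                             cfg$normal_group,
                                             cfg$tumour_group)))
    p <- file.path(cfg$out_dir, "group_stats.tsv")
    write_tsv(gs, p, hdr); outs["group_stats"] <- p

    folds <- stage("fold_to_normal",
                   fold_to_normal_median(nm$counts[rownames(x), , drop = FALSE],
                                         normals))
    p <- file.path(cfg$out_dir, "fold_to_normal_median.tsv")
    write_tsv(data.frame(gene_id = rownames(folds),
                         as.data.frame(folds, check.names = FALSE)), p, hdr)
    outs["fold_to_normal"] <- p

    bs <- do.call(rbind, lapply(rownames(folds), function(g) {
      do.call(rbind, lapply(c(cfg$normal_group, cfg$tumour_group),
                            function(grp) {
        ids <- meta$sample_id[meta$group == grp]
        if (length(ids) < 4) return(NULL)
        b <- boxplot_summary(folds[g, ids], gene_id = g, group = grp)
        data.frame(gene_id = g, group = grp, q1 = b$q1, median = b$median,
                   q3 = b$q3, iqr = b$iqr, n_outliers = length(b$outliers),
                   stringsAsFactors = FALSE)
      }))
    }))
    p <- file.path(cfg$out_dir, "boxplot_summaries.tsv")
    write_tsv(bs, p, hdr); outs["boxplot_summaries"] <- p
  }
  invisible(outs)
}
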