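# Independent brute-force oracles and random-instance builders.
# These deliberately share no code with the package internals: plain loops,
# no interval packages, no graph library.

# all-pairs overlap fraction of two single rows (smaller-peak denominator)
oracle_ovfrac <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0)
  inter <- max(0, min(e1, e2) - max(s1, s2))
  inter / min(e1 - s1, e2 - s2)
}

# brute-force replicate consensus: all pairs + BFS connected components
oracle_consensus <- function(rep1, rep2, min_frac = 0.5, max_fdr = 10,
                             min_td = 15) {
  n1 <- nrow(rep1); n2 <- nrow(rep2)
  edges <- list()
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    f <- oracle_ovfrac(rep1$chrom[i], rep1$start[i], rep1$end[i],
                       rep2$chrom[j], rep2$start[j], rep2$end[j])
    if (f < min_frac) next
    g1 <- rep1$fdr[i] < max_fdr && rep1$tag_density[i] > min_td
    g2 <- rep2$fdr[j] < max_fdr && rep2$tag_density[j] > min_td
    if (g1 || g2) edges[[length(edges) + 1]] <- c(i, j + n1)
  }
  if (!length(edges)) return(data.frame(chrom = character(),
                                        start = numeric(), end = numeric()))
  adj <- lapply(seq_len(n1 + n2), function(k) integer())
  for (e in edges) {
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    adj[[e[2]]] <- c(adj[[e[2]]], e[1])
  }
  seen <- rep(FALSE, n1 + n2)
  regions <- list()
  for (v in seq_len(n1 + n2)) {
    if (seen[v] || !length(adj[[v]])) next
    comp <- integer(); queue <- v; seen[v] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      comp <- c(comp, u)
      for (w in adj[[u]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    i1 <- comp[comp <= n1]; i2 <- comp[comp > n1] - n1
    st <- c(rep1$start[i1], rep2$start[i2]); en <- c(rep1$end[i1], rep2$end[i2])
    regions[[length(regions) + 1]] <-
      data.frame(chrom = rep1$chrom[i1[1]], start = min(st), end = max(en))
  }
  out <- do.call(rbind, regions)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# exhaustive nearest-gene scan (loops over every peak x gene pair)
oracle_annotate <- function(peaks, genes, upstream = 5000, downstream = 1000,
                            promoter_pad = 1000) {
  res <- data.frame(peak_id = peaks$peak_id, gene_id = NA_character_,
                    distance_to_tss = NA_real_, stringsAsFactors = FALSE)
  for (p in seq_len(nrow(peaks))) {
    best_g <- NA_character_; best_d <- Inf; best_signed <- NA_real_
    for (g in seq_len(nrow(genes))) {
      if (peaks$chrom[p] != genes$chrom[g]) next
      dir <- if (genes$strand[g] == "+") 1 else -1
      d <- (peaks$summit[p] - genes$tss[g]) * dir
      in_window <- d >= -upstream && d <= downstream
      u <- genes$utr5[[g]]
      if (genes$strand[g] == "+") {
        cs <- max(0, genes$tss[g] - 1000)
        ce <- if (!is.null(u)) max(genes$tss[g], u[2]) else genes$tss[g]
      } else {
        ce <- genes$tss[g] + 1000
        cs <- if (!is.null(u)) min(genes$tss[g], u[1]) else genes$tss[g]
      }
      in_pad <- max(0, min(peaks$end[p], ce + promoter_pad) -
                         max(peaks$start[p], cs - promoter_pad)) > 0
      if (!in_window && !in_pad) next
      if (abs(d) < best_d ||
          (abs(d) == best_d && genes$gene_id[g] < best_g)) {
        best_d <- abs(d); best_g <- genes$gene_id[g]; best_signed <- d
      }
    }
    res$gene_id[p] <- best_g
    res$distance_to_tss[p] <- best_signed
  }
  res
}

# textbook pooled-variance two-sample t statistic
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# random peak-set pair for property tests
random_peak_sets <- function(n_max = 50) {
  mk <- function(lab) {
    n <- sample.int(n_max, 1)
    start <- sample.int(20000, n, replace = TRUE)
    len <- sample(50:500, n, replace = TRUE)
    peak_set(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             start = start, end = start + len,
             summit = start + floor(len / 2),
             fdr = runif(n, 0, 20), tag_density = runif(n, 0, 40),
             label = lab)
  }
  list(rep1 = mk("r1"), rep2 = mk("r2"))
}

# random gene set (with occasional 5' UTRs) for annotation property tests
random_gene_set <- function(n_max = 15) {
  n <- sample.int(n_max, 1)
  start <- sample.int(50000, n, replace = TRUE)
  len <- sample(1000:5000, n, replace = TRUE)
  utr <- lapply(seq_len(n), function(i) {
    if (runif(1) < 0.5) NULL else c(start[i], start[i] + 200)
  })
  gene_set(gene_id = sprintf("g%02d", seq_len(n)),
           chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
           strand = sample(c("+", "-"), n, replace = TRUE),
           start = start, end = start + len, utr5 = utr)
}

# small count matrix with hand-controllable probe values
toy_counts <- function(endo, ref, pos, meta = NULL) {
  m <- rbind(endo, ref, pos)
  count_matrix(m, c(rep("endogenous", nrow(endo)),
                    rep("reference", nrow(ref)),
                    rep("positive_control", nrow(pos))), meta)
}
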