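#' High-sensitivity peak filter for pooled-replicate peak calls
#'
#' Applied to peaks called on reads pooled across replicates: retains peaks
#' with FDR strictly below `max_fdr` percent AND tag density strictly above
#' `min_td`. Both comparisons are strict, exactly as the thresholds are
#' usually printed (FDR < 10, TD > 30).
#'
#' @param peaks a [peak_set()].
#' @param max_fdr maximum FDR, percent scale. Default 10.
#' @param min_td minimum tag density. Default 30 (pooled-reads setting).
#' @return the retained subset, still a `PeakSet`.
#' @export
filter_high_sensitivity <- function(peaks, max_fdr = 10, min_td = 30) {
  stopifnot(inherits(peaks, "PeakSet"))
  if (max_fdr < 0 || min_td < 0) stop("thresholds must be non-negative")
  keep <- peaks$fdr < max_fdr & peaks$tag_density > min_td
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, label = attr(peaks, "label"),
            class = c("PeakSet", "data.frame"))
}

# All cross-set peak pairs whose smaller-peak overlap fraction meets min_frac.
# Returns a data.frame of (i, j, frac) indices into a and b.
qualifying_pairs <- function(a, b, min_frac) {
  hits <- GenomicRanges::findOverlaps(peaks_as_granges(a), peaks_as_granges(b))
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  if (!length(i)) return(data.frame(i = integer(), j = integer(),
                                    frac = numeric()))
  frac <- overlap_fraction(a[i, , drop = FALSE], b[j, , drop = FALSE])
  keep <- frac >= min_frac
  data.frame(i = i[keep], j = j[keep], frac = frac[keep])
}

#' Replicate-consensus ("high confidence") peak calling
#'
#' Identifies binding regions supported by both experimental replicates.
#' The rule has three parts: (1) a peak pair (one per replicate) overlaps when
#' at least `min_frac` of the *smaller* peak is covered by the larger
#' ([overlap_fraction()]); (2) a pair qualifies when at least one of its two
#' peaks has FDR < `max_fdr` AND tag density > `min_td` (strict); (3) each
#' connected component of the qualifying-pair graph that contains peaks from
#' both replicates becomes one consensus region, reported as the union
#' interval of its member peaks with the summit taken from the member with the
#' highest tag density.
#'
#' @param rep1,rep2 non-empty [peak_set()]s, one per replicate.
#' @param min_frac minimum smaller-peak overlap fraction. Default 0.5.
#' @param max_fdr FDR gate, percent. Default 10.
#' @param min_td tag-density gate. Default 15.
#' @return an object of class `ConsensusResult`: list with `regions` (a
#'   `PeakSet` of merged consensus regions), `support` (per-region list with
#'   the contributing `peak_id`s from each replicate) and `n_high_confidence`.
#' @examples
#' r1 <- peak_set("chr1", 100, 200, 150, fdr = 5, tag_density = 20, label = "rep1")
#' r2 <- peak_set("chr1", 150, 250, 200, fdr = 12, tag_density = 10, label = "rep2")
#' replicate_consensus(r1, r2)
#' @export
replicate_consensus <- function(rep1, rep2, min_frac = 0.5,
                                max_fdr = 10, min_td = 15) {
  stopifnot(inherits(rep1, "PeakSet"), inherits(rep2, "PeakSet"))
  if (nrow(rep1) == 0 || nrow(rep2) == 0)
    stop("consensus undefined: empty replicate peak set")
  if (min_frac < 0 || min_frac > 1) stop("min_frac must be in [0, 1]")
  if (max_fdr < 0 || min_td < 0) stop("thresholds must be non-negative")

  pairs <- qualifying_pairs(rep1, rep2, min_frac)
  pass1 <- rep1$fdr < max_fdr & rep1$tag_density > min_td
  pass2 <- rep2$fdr < max_fdr & rep2$tag_density > min_td
  keep <- pass1[pairs$i] | pass2[pairs$j]
  pairs <- pairs[keep, , drop = FALSE]

  if (!nrow(pairs)) {
    empty <- peak_set(character(), numeric(), numeric(), numeric(),
                      numeric(), numeric(), label = "consensus")
    return(structure(list(regions = empty, support = list(),
                          n_high_confidence = 0L),
                     class = "ConsensusResult"))
  }

  # connected components over the bipartite qualifying-pair graph
  v1 <- paste0("a", pairs$i); v2 <- paste0("b", pairs$j)
  g <- igraph::graph_from_data_frame(data.frame(v1, v2), directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership

  regions <- vector("list", comp$no)
  support <- vector("list", comp$no)
  for (k in seq_len(comp$no)) {
    vs <- names(memb)[memb == k]
    i1 <- as.integer(sub("^a", "", vs[startsWith(vs, "a")]))
    i2 <- as.integer(sub("^b", "", vs[startsWith(vs, "b")]))
    members <- rbind(as.data.frame(rep1[i1, , drop = FALSE]),
                     as.data.frame(rep2[i2, , drop = FALSE]))
    best <- members[order(-members$tag_density, members$peak_id), ][1, ]
    regions[[k]] <- data.frame(chrom = members$chrom[1],
                               start = min(members$start),
                               end = max(members$end),
                               summit = best$summit,
                               fdr = min(members$fdr),
                               tag_density = max(members$tag_density),
                               stringsAsFactors = FALSE)
    support[[k]] <- list(rep1 = sort(rep1$peak_id[i1]),
                         rep2 = sort(rep2$peak_id[i2]))
  }
  reg <- do.call(rbind, regions)
  ord <- order(reg$chrom, reg$start, reg$end)
  reg <- reg[ord, , drop = FALSE]
  support <- support[ord]
  out <- peak_set(chrom = reg$chrom, start = reg$start, end = reg$end,
                  summit = reg$summit, fdr = reg$fdr,
                  tag_density = reg$tag_density,
                  peak_id = sprintf("consensus_%d", seq_len(nrow(reg))),
                  label = "consensus")
  names(support) <- out$peak_id
  structure(list(regions = out, support = support,
                 n_high_confidence = nrow(out)),
            class = "ConsensusResult")
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("ConsensusResult: %d high-confidence consensus region(s)\n",
              x$n_high_confidence))
  if (x$n_high_confidence)
    print.data.frame(utils::head(as.data.frame(x$regions), 10))
  invisible(x)
}

#' Shared/unique classification of two peak sets
#'
#' Classifies every peak of each set as *shared* (it has at least one partner
#' in the other set with smaller-peak overlap fraction >= `min_frac`) or
#' *unique*. Used to compare cistromes across cell types.
#'
#' @param a,b [peak_set()]s.
#' @param min_frac minimum smaller-peak overlap fraction. Default 0.5.
#' @return an object of class `SetComparison`: list with `PeakSet`s
#'   `shared_a`, `unique_a`, `shared_b`, `unique_b` and a `counts` vector.
#' @export
compare_peak_sets <- function(a, b, min_frac = 0.5) {
  stopifnot(inherits(a, "PeakSet"), inherits(b, "PeakSet"))
  if (min_frac < 0 || min_frac > 1) stop("min_frac must be in [0, 1]")
  pairs <- qualifying_pairs(a, b, min_frac)
  sa <- seq_len(nrow(a)) %in% pairs$i
  sb <- seq_len(nrow(b)) %in% pairs$j
  subset_ps <- function(ps, keep, lab) {
    out <- ps[keep, , drop = FALSE]
    rownames(out) <- NULL
    structure(out, label = lab, class = c("PeakSet", "data.frame"))
  }
  la <- attr(a, "label"); lb <- attr(b, "label")
  structure(list(
    shared_a = subset_ps(a, sa, paste0(la, "_shared")),
    unique_a = subset_ps(a, !sa, paste0(la, "_unique")),
    shared_b = subset_ps(b, sb, paste0(lb, "_shared")),
    unique_b = subset_ps(b, !sb, paste0(lb, "_unique")),
    counts = c(shared_a = sum(sa), unique_a = sum(!sa),
               shared_b = sum(sb), unique_b = sum(!sb))
  ), class = "SetComparison")
}

#' @export
print.SetComparison <- function(x, ...) {
  cat("SetComparison:\n")
  print(x$counts)
  invisible(x)
}
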