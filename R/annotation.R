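#' Assign the nearest gene to each peak via TSS windows
#'
#' A gene is a candidate for a peak when the peak *summit* lies within the
#' strand-oriented window from `upstream` bp before to `downstream` bp after
#' the gene's transcription start site (TSS), or when the peak *interval*
#' comes within `promoter_pad` bp of the gene's core promoter (the 5' UTR plus
#' 1 kb upstream of the TSS). Among candidates the gene with the smallest
#' absolute summit-to-TSS distance wins; ties go to the lexicographically
#' smallest `gene_id`. Distances are signed in gene orientation: negative
#' means upstream of the TSS.
#'
#' @param peaks a [peak_set()].
#' @param genes a non-empty [gene_set()].
#' @param upstream,downstream TSS window extents in bp (defaults 5000 / 1000).
#' @param promoter_pad pad around the core promoter in bp (default 1000).
#' @return a data frame with one row per peak: `peak_id`, `gene_id` (`NA` if
#'   unassigned), `relation` (`upstream_window`, `downstream_window`,
#'   `promoter_proximal` or `unassigned`), `distance_to_tss` (signed bp, `NA`
#'   if unassigned) and `alternates` (comma-separated other candidate genes).
#' @examples
#' g <- gene_set("geneA", "chr1", "+", 10000, 20000)
#' p <- peak_set("chr1", 5900, 6100, 6000, 5, 20)
#' assign_nearest_gene(p, g)   # distance -4000, upstream_window
#' @export
assign_nearest_gene <- function(peaks, genes, upstream = 5000,
                                downstream = 1000, promoter_pad = 1000) {
  stopifnot(inherits(peaks, "PeakSet"), inherits(genes, "GeneSet"))
  if (nrow(genes) == 0) stop("gene set is empty")
  if (upstream < 0 || downstream < 0 || promoter_pad < 0)
    stop("windows must be non-negative")

  # oriented summit-to-TSS distance for every (peak, gene) candidate pair
  dir <- ifelse(genes$strand == "+", 1, -1)

  # TSS-window candidates: summit within [tss - upstream, tss + downstream]
  # in oriented coordinates -> genomic interval depends on strand
  win_lo <- ifelse(dir == 1, genes$tss - upstream, genes$tss - downstream)
  win_hi <- ifelse(dir == 1, genes$tss + downstream, genes$tss + upstream)
  lev <- union(peaks$chrom, genes$chrom)
  win_gr <- GenomicRanges::GRanges(factor(genes$chrom, lev),
                                   IRanges::IRanges(win_lo + 1, win_hi + 1))
  summit_gr <- GenomicRanges::GRanges(factor(peaks$chrom, lev),
                                      IRanges::IRanges(peaks$summit + 1,
                                                       peaks$summit + 1))
  h1 <- GenomicRanges::findOverlaps(summit_gr, win_gr)
  cand <- data.frame(p = S4Vectors::queryHits(h1),
                     g = S4Vectors::subjectHits(h1),
                     via_window = rep(TRUE, length(h1)))

  # promoter-pad candidates: peak interval within promoter_pad of the
  # core promoter (equivalently, overlaps the padded promoter interval)
  cp <- core_promoter(genes)
  pad_gr <- GenomicRanges::GRanges(factor(cp$chrom, lev),
                                   IRanges::IRanges(cp$start - promoter_pad + 1,
                                                    cp$end + promoter_pad))
  peaks_gr <- GenomicRanges::GRanges(factor(peaks$chrom, lev),
                                     IRanges::IRanges(peaks$start + 1,
                                                      peaks$end))
  h2 <- GenomicRanges::findOverlaps(peaks_gr, pad_gr)
  cand2 <- data.frame(p = S4Vectors::queryHits(h2),
                      g = S4Vectors::subjectHits(h2),
                      via_window = rep(FALSE, length(h2)))
  cand <- rbind(cand, cand2)

  n <- nrow(peaks)
  out <- data.frame(peak_id = peaks$peak_id,
                    gene_id = NA_character_,
                    relation = "unassigned",
                    distance_to_tss = NA_real_,
                    alternates = "",
                    stringsAsFactors = FALSE)
  if (!nrow(cand)) return(out)

  cand$dist <- (peaks$summit[cand$p] - genes$tss[cand$g]) * dir[cand$g]
  for (p in unique(cand$p)) {
    rows <- cand[cand$p == p, , drop = FALSE]
    # collapse duplicate genes reachable via both clauses; a window hit
    # determines the relation label
    agg <- stats::aggregate(via_window ~ g + dist, data = rows, FUN = any)
    gid <- genes$gene_id[agg$g]
    ord <- order(abs(agg$dist), gid)
    agg <- agg[ord, , drop = FALSE]; gid <- gid[ord]
    out$gene_id[p] <- gid[1]
    out$distance_to_tss[p] <- agg$dist[1]
    out$relation[p] <- if (!agg$via_window[1]) "promoter_proximal"
                       else if (agg$dist[1] < 0) "upstream_window"
                       else "downstream_window"
    if (length(gid) > 1) out$alternates[p] <- paste(gid[-1], collapse = ",")
  }
  out
}

#' Genomic feature distribution of peak summits versus genome background
#'
#' Classifies every peak by the genomic feature its *summit* falls in, with
#' precedence core promoter > exon > intron > 1 kb downstream of the gene end
#' > distal intergenic, and tallies the genome-wide base-pair occupancy of the
#' same feature classes (same precedence) as the background distribution.
#' The core promoter is the 5' UTR plus 1 kb upstream of the TSS.
#'
#' @param peaks a [peak_set()].
#' @param genes a [gene_set()].
#' @param genome_lengths named numeric vector of chromosome lengths in bp,
#'   covering every chromosome peaks sit on.
#' @return an object of class `FeatureDistribution`: list with
#'   `observed_fraction` and `background_fraction` (named vectors over the five
#'   classes, each summing to 1), `class_of_peak` (per-peak class) and
#'   `background_bp`.
#' @export
feature_distribution <- function(peaks, genes, genome_lengths) {
  stopifnot(inherits(peaks, "PeakSet"), inherits(genes, "GeneSet"))
  classes <- c("core_promoter", "exon", "intron", "downstream_1kb",
               "distal_intergenic")
  miss <- setdiff(unique(c(peaks$chrom, genes$chrom)), names(genome_lengths))
  if (length(miss))
    stop("peak chromosome(s) absent from genome_lengths: ",
         paste(miss, collapse = ", "))

  lev <- names(genome_lengths)
  mk <- function(chrom, start, end) {
    keep <- end > start
    GenomicRanges::GRanges(factor(chrom[keep], levels = lev),
                           IRanges::IRanges(start[keep] + 1, end[keep]))
  }
  genome_gr <- mk(names(genome_lengths), rep(0, length(genome_lengths)),
                  as.numeric(genome_lengths))
  clip <- function(gr) {
    if (!length(gr)) return(gr)
    GenomicRanges::intersect(gr, genome_gr)
  }

  cp <- core_promoter(genes)
  cp_gr <- clip(mk(cp$chrom, pmax(0, cp$start), cp$end))
  ex <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    e <- genes$exons[[i]]
    if (is.null(e) || !nrow(e)) return(NULL)
    data.frame(chrom = genes$chrom[i], start = e[, 1], end = e[, 2])
  }))
  ex_gr <- if (is.null(ex)) mk(character(), numeric(), numeric())
           else clip(mk(ex$chrom, ex$start, ex$end))
  body_gr <- clip(mk(genes$chrom, genes$start, genes$end))
  ds_lo <- ifelse(genes$strand == "+", genes$tes, genes$tes - 1000)
  ds_hi <- ifelse(genes$strand == "+", genes$tes + 1000, genes$tes)
  ds_gr <- clip(mk(genes$chrom, pmax(0, ds_lo), ds_hi))

  # precedence peeling: each class keeps only bp not claimed above it
  lay <- list(core_promoter = GenomicRanges::reduce(cp_gr))
  claimed <- lay$core_promoter
  peel <- function(gr) {
    gr <- GenomicRanges::setdiff(GenomicRanges::reduce(gr), claimed)
    claimed <<- GenomicRanges::reduce(c(claimed, gr))
    gr
  }
  lay$exon <- peel(ex_gr)
  lay$intron <- peel(body_gr)
  lay$downstream_1kb <- peel(ds_gr)
  lay$distal_intergenic <- GenomicRanges::setdiff(genome_gr, claimed)

  bp <- vapply(lay, function(gr) sum(as.numeric(GenomicRanges::width(gr))),
               numeric(1))
  background <- bp / sum(as.numeric(genome_lengths))

  cls <- rep("distal_intergenic", nrow(peaks))
  if (nrow(peaks)) {
    summit_gr <- mk(peaks$chrom, peaks$summit, peaks$summit + 1)
    for (cl in c("downstream_1kb", "intron", "exon", "core_promoter")) {
      hit <- IRanges::overlapsAny(summit_gr, lay[[cl]])
      cls[hit] <- cl
    }
  }
  observed <- vapply(classes, function(cl) mean(cls == cl), numeric(1))
  if (!nrow(peaks)) observed[] <- NA_real_

  structure(list(observed_fraction = observed,
                 background_fraction = background[classes],
                 class_of_peak = stats::setNames(cls, peaks$peak_id),
                 background_bp = bp[classes]),
            class = "FeatureDistribution")
}

#' @export
print.FeatureDistribution <- function(x, ...) {
  cat("FeatureDistribution (observed vs background fractions):\n")
  print(round(rbind(observed = x$observed_fraction,
                    background = x$background_fraction), 4))
  invisible(x)
}
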