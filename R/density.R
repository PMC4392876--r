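#' Read single-base tag positions from 4-column BED
#'
#' Tags are the 5' ends of aligned sequencing reads, stored one base per row
#' as `chrom, pos, pos+1, count` (0-based half-open; `count` defaults to 1
#' when the fourth column is absent).
#'
#' @param path file path.
#' @return a data frame with columns `chrom`, `pos`, `count`.
#' @export
read_tags <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("tag BED needs at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    pos = as.numeric(df[[2]]),
                    count = if (ncol(df) >= 4) as.numeric(df[[4]]) else 1,
                    stringsAsFactors = FALSE)
  if (any(df[[3]] != out$pos + 1))
    stop("tag BED rows must be single-base (end == start + 1)")
  out
}

#' Summit-centred binned tag-density matrix
#'
#' For each peak, counts tags falling in fixed-width bins across a window
#' extending `flank` bp either side of the peak summit: bin `j` (1-based)
#' covers `[summit - flank + (j-1)*bin_size, summit - flank + j*bin_size)`.
#' At the defaults (5 kb flank, 50 bp bins) this is the 200-bin layout used
#' for tag-density heatmaps around binding sites. Peaks are unstranded; bins
#' always run left to right in genome coordinates.
#'
#' @param tags data frame with `chrom`, `pos` and optionally `count`
#'   (as from [read_tags()]).
#' @param peaks a [peak_set()].
#' @param flank half-window in bp; must be divisible by `bin_size`.
#'   Default 5000.
#' @param bin_size bin width in bp. Default 50.
#' @return an object of class `DensityMatrix`: a numeric matrix
#'   (peaks x bins, rownames = peak ids) with attributes `flank`, `bin_size`
#'   and `bin_offsets` (left edge of each bin relative to the summit).
#' @export
density_matrix <- function(tags, peaks, flank = 5000, bin_size = 50) {
  stopifnot(inherits(peaks, "PeakSet"))
  if (flank <= 0 || bin_size <= 0) stop("flank and bin_size must be positive")
  if (flank %% bin_size != 0) stop("flank must be divisible by bin_size")
  if (is.null(tags$count)) tags$count <- 1
  nbin <- as.integer(2 * flank / bin_size)
  m <- matrix(0, nrow = nrow(peaks), ncol = nbin,
              dimnames = list(peaks$peak_id, NULL))
  by_chr <- split(tags[c("pos", "count")], tags$chrom)
  for (i in seq_len(nrow(peaks))) {
    tg <- by_chr[[peaks$chrom[i]]]
    if (is.null(tg) || !nrow(tg)) next
    rel <- tg$pos - (peaks$summit[i] - flank)
    keep <- rel >= 0 & rel < 2 * flank
    if (!any(keep)) next
    bin <- rel[keep] %/% bin_size + 1
    acc <- tapply(tg$count[keep], bin, sum)
    m[i, as.integer(names(acc))] <- as.numeric(acc)
  }
  structure(m, flank = flank, bin_size = bin_size,
            bin_offsets = seq(-flank, flank - bin_size, by = bin_size),
            class = c("DensityMatrix", "matrix"))
}

#' Mean tag-density profile across peaks
#'
#' @param m a [density_matrix()].
#' @return numeric vector of per-bin column means, named by bin offset from
#'   the summit.
#' @export
mean_profile <- function(m) {
  stopifnot(inherits(m, "DensityMatrix"))
  if (nrow(m) == 0) stop("empty density matrix")
  stats::setNames(colMeans(m), attr(m, "bin_offsets"))
}

#' Heatmap display order: rows by descending total signal
#'
#' @param m a [density_matrix()].
#' @return character vector of peak ids, strongest first; ties broken by
#'   peak id.
#' @export
order_rows_by_signal <- function(m) {
  stopifnot(inherits(m, "DensityMatrix"))
  if (nrow(m) == 0) return(character())
  tot <- rowSums(m)
  rownames(m)[order(-tot, rownames(m))]
}

#' Plot a summit-centred tag-density heatmap and mean profile
#'
#' Base-graphics rendering of a [density_matrix()]: rows ordered by
#' [order_rows_by_signal()], plus the mean profile underneath.
#'
#' @param x a `DensityMatrix`.
#' @param main plot title.
#' @param ... ignored.
#' @return invisibly, the row order used.
#' @export
plot.DensityMatrix <- function(x, main = "Tag density around summits", ...) {
  ord <- order_rows_by_signal(x)
  m <- x[ord, , drop = FALSE]
  off <- attr(x, "bin_offsets")
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::image(x = off, y = seq_len(nrow(m)), z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  xlab = "bp from summit", ylab = "peaks (by signal)",
                  main = main, col = grDevices::hcl.colors(64, "Blues 3",
                                                           rev = TRUE))
  graphics::plot(off, colMeans(x), type = "l", xlab = "bp from summit",
                 ylab = "mean tags/bin")
  invisible(ord)
}
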