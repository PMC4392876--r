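#' Construct a set of called binding regions
#'
#' A `PeakSet` is the package's container for called transcription-factor
#' binding regions ("peaks"). Coordinates are 0-based, half-open
#' (`start` inclusive, `end` exclusive), the convention BED files use.
#' Each peak carries the single-base summit of maximal enrichment, the peak
#' caller's false discovery rate on the MACS-style percent scale (0-100), and
#' the tag density (number of sequencing tags supporting the region).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open, `start < end`.
#' @param summit integer vector of absolute summit coordinates,
#'   `start <= summit < end`.
#' @param fdr numeric vector, percent scale (0-100), non-negative.
#' @param tag_density numeric vector, non-negative.
#' @param peak_id character vector of unique identifiers; generated from
#'   `label` if omitted.
#' @param source optional replicate / cell-line label per peak.
#' @param label a label for the whole set.
#' @return a data frame of class `PeakSet` with columns `peak_id`, `chrom`,
#'   `start`, `end`, `summit`, `fdr`, `tag_density`, `source`, sorted by
#'   `(chrom, start)`, with the set label in `attr(, "label")`.
#' @examples
#' peak_set(chrom = "chr1", start = 100, end = 200, summit = 150,
#'          fdr = 5, tag_density = 20)
#' @export
peak_set <- function(chrom, start, end, summit, fdr, tag_density,
                     peak_id = NULL, source = NULL, label = "peaks") {
  start <- as.numeric(start); end <- as.numeric(end)
  summit <- as.numeric(summit)
  n <- length(start)
  # scalars recycle across peaks
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(fdr) == 1) fdr <- rep(fdr, n)
  if (length(tag_density) == 1) tag_density <- rep(tag_density, n)
  fdr <- as.numeric(fdr); tag_density <- as.numeric(tag_density)
  if (is.null(peak_id)) peak_id <- sprintf("%s_%d", label, seq_len(n))
  if (is.null(source)) source <- rep(label, n)
  stopifnot(length(start) == n, length(end) == n, length(summit) == n,
            length(fdr) == n, length(tag_density) == n,
            length(peak_id) == n, length(source) == n)
  if (anyDuplicated(peak_id))
    stop("peak_ids must be unique within a PeakSet")
  bad <- which(!(start < end))
  if (length(bad))
    stop("peak(s) with start >= end (zero or negative length): ",
         paste(peak_id[bad], collapse = ", "))
  bad <- which(summit < start | summit >= end)
  if (length(bad))
    stop("summit outside [start, end) for peak(s): ",
         paste(peak_id[bad], collapse = ", "))
  if (any(fdr < 0)) stop("fdr must be >= 0 (percent scale)")
  if (any(tag_density < 0)) stop("tag_density must be >= 0")
  df <- data.frame(peak_id = as.character(peak_id), chrom = as.character(chrom),
                   start = start, end = end, summit = summit, fdr = fdr,
                   tag_density = tag_density, source = as.character(source),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end, df$peak_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, label = label, class = c("PeakSet", "data.frame"))
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d peak(s) on %d chromosome(s)\n",
              attr(x, "label"), nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' @export
summary.PeakSet <- function(object, ...) {
  cat(sprintf("PeakSet '%s': %d peaks\n", attr(object, "label"), nrow(object)))
  if (nrow(object)) {
    cat(sprintf("  width: median %g bp   fdr: median %g%%   tag density: median %g\n",
                stats::median(object$end - object$start),
                stats::median(object$fdr), stats::median(object$tag_density)))
  }
  invisible(object)
}

# GRanges view of a PeakSet (1-based closed, as GenomicRanges expects)
peaks_as_granges <- function(ps) {
  GenomicRanges::GRanges(ps$chrom,
                         IRanges::IRanges(start = ps$start + 1, end = ps$end))
}

#' Fraction of the smaller peak covered by the overlap
#'
#' The reciprocal-overlap measure used for replicate consensus and
#' cross-cell-type comparison: the length of the intersection divided by the
#' length of the *shorter* of the two regions. Symmetric by construction.
#' Cross-chromosome pairs have overlap 0. Vectorised over pairs.
#'
#' @param a,b `PeakSet` rows (or any data frames with `chrom`, `start`, `end`),
#'   recycled to a common length.
#' @return numeric vector of fractions in \[0, 1\].
#' @examples
#' a <- peak_set("chr1", 100, 200, 150, 5, 20)
#' b <- peak_set("chr1", 150, 250, 200, 5, 20)
#' overlap_fraction(a, b)  # 0.5
#' @export
overlap_fraction <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  inter <- pmax(0, pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]))
  inter[a$chrom[ai] != b$chrom[bi]] <- 0
  smaller <- pmin(a$end[ai] - a$start[ai], b$end[bi] - b$start[bi])
  inter / smaller
}

#' Read peaks from a delimited BED-dialect file
#'
#' Reads tab-delimited peak tables of the shape MACS-style callers emit:
#' `chrom`, `start`, `end`, `name`, `tag_density`, `strand`, plus
#' `summit_offset` (or `summit`) and `fdr_percent` (or `fdr`) columns. BED
#' coordinates are taken as-is (already 0-based half-open).
#'
#' @param path file path.
#' @param summit_dialect `"offset"` if the summit column stores the offset from
#'   `start` (MACS convention), `"absolute"` if it stores the genomic
#'   coordinate.
#' @param label label for the resulting set (defaults to the file name).
#' @return a [peak_set()].
#' @export
read_peaks <- function(path, summit_dialect = c("offset", "absolute"),
                       label = NULL) {
  summit_dialect <- match.arg(summit_dialect)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need_one <- function(alts) {
    hit <- intersect(alts, names(df))
    if (!length(hit))
      stop("missing column (one of ", paste(alts, collapse = "/"),
           ") in ", path)
    hit[1]
  }
  c_chrom <- need_one("chrom"); c_start <- need_one("start")
  c_end <- need_one("end")
  c_sum <- need_one(c("summit_offset", "summit"))
  c_fdr <- need_one(c("fdr_percent", "fdr"))
  c_td <- need_one(c("tag_density", "td", "score"))
  for (col in c(c_start, c_end, c_sum, c_fdr, c_td)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop(sprintf("malformed value in column '%s' at line %d of %s",
                   col, which(is.na(v))[1] + 1L, path))
    df[[col]] <- v
  }
  summit <- if (summit_dialect == "offset") df[[c_start]] + df[[c_sum]]
            else df[[c_sum]]
  ids <- if ("name" %in% names(df)) as.character(df$name) else NULL
  bad <- which(!(df[[c_start]] < df[[c_end]]))
  if (length(bad))
    stop(sprintf("start >= end at line %d of %s", bad[1] + 1L, path))
  bad <- which(summit < df[[c_start]] | summit >= df[[c_end]])
  if (length(bad))
    stop(sprintf("summit outside interval at line %d of %s", bad[1] + 1L, path))
  peak_set(chrom = df[[c_chrom]], start = df[[c_start]], end = df[[c_end]],
           summit = summit, fdr = df[[c_fdr]], tag_density = df[[c_td]],
           peak_id = ids, label = label)
}

#' Write a PeakSet to the BED-dialect format [read_peaks()] consumes
#'
#' @param ps a `PeakSet`.
#' @param path output file path.
#' @param header_lines optional character vector of `#`-prefixed provenance
#'   lines written before the column header.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(ps, path, header_lines = NULL) {
  out <- data.frame(chrom = ps$chrom, start = ps$start, end = ps$end,
                    name = ps$peak_id, tag_density = ps$tag_density,
                    strand = rep(".", nrow(ps)),
                    summit_offset = ps$summit - ps$start,
                    fdr_percent = ps$fdr, stringsAsFactors = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
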