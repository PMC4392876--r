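#' Construct a set of gene models
#'
#' A `GeneSet` holds stranded gene models used for peak annotation and for the
#' genomic feature distribution. Coordinates are 0-based half-open internally.
#' The transcription start site (TSS) is the `start` coordinate for `+` strand
#' genes and the `end` coordinate for `-` strand genes; `tes` is the opposite
#' end. Exons and the 5' UTR are optional and used only by
#' [feature_distribution()] / the core-promoter definition.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom,strand character vectors; strand one of `"+"`, `"-"`.
#' @param start,end numeric; 0-based half-open gene extent, `start < end`.
#' @param exons list (one element per gene) of two-column matrices
#'   `cbind(start, end)` of non-overlapping exon intervals within the gene, or
#'   `NULL`. Defaults to the whole gene body as a single exon.
#' @param utr5 list of length-2 vectors `c(start, end)` for the 5' UTR, or
#'   `NULL` per gene.
#' @return a data frame of class `GeneSet` with columns `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `tss`, `tes` and list columns `exons`, `utr5`.
#' @export
gene_set <- function(gene_id, chrom, strand, start, end,
                     exons = NULL, utr5 = NULL) {
  n <- length(gene_id)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(strand) == 1) strand <- rep(strand, n)
  stopifnot(length(chrom) == n, length(strand) == n,
            length(start) == n, length(end) == n)
  if (anyDuplicated(gene_id)) stop("gene_ids must be unique")
  if (!all(strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "))
  if (any(start >= end)) stop("gene start must be < end")
  if (is.null(exons))
    exons <- lapply(seq_len(n), function(i) cbind(start[i], end[i]))
  if (is.null(utr5)) utr5 <- vector("list", n)
  stopifnot(length(exons) == n, length(utr5) == n)
  for (i in seq_len(n)) {
    ex <- exons[[i]]
    if (is.null(ex)) { exons[[i]] <- cbind(start[i], end[i]); next }
    ex <- matrix(as.numeric(ex), ncol = 2)
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    if (any(ex[, 1] >= ex[, 2]) || any(ex[, 1] < start[i]) ||
        any(ex[, 2] > end[i]))
      stop("exons of ", gene_id[i], " not within gene body")
    if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2]))
      stop("exons of ", gene_id[i], " overlap")
    exons[[i]] <- ex
  }
  tss <- ifelse(strand == "+", start, end)
  tes <- ifelse(strand == "+", end, start)
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   strand = as.character(strand), start = start, end = end,
                   tss = tss, tes = tes, stringsAsFactors = FALSE)
  df$exons <- exons
  df$utr5 <- utr5
  df <- df[order(df$chrom, df$start, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("GeneSet", "data.frame"))
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet: %d gene(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x))
    print.data.frame(utils::head(
      as.data.frame(x)[c("gene_id", "chrom", "strand", "start", "end", "tss")],
      10))
  invisible(x)
}

#' Read gene models from GTF or BED12
#'
#' GTF input (1-based closed) is converted to the internal 0-based half-open
#' convention; `exon` features define exons and `five_prime_utr`/`5UTR`
#' features the 5' UTR. BED12 input is taken as-is, with blocks as exons and
#' the region between the transcript start and `thickStart` (strand-oriented)
#' as the 5' UTR. Parsing is delegated to \pkg{rtracklayer}.
#'
#' @param path file path ending in `.gtf`/`.gff` or `.bed`.
#' @param format `"gtf"` or `"bed12"`; guessed from the extension by default.
#' @return a [gene_set()]; empty input yields an empty set with a warning.
#' @export
read_genes <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gtf"
  }
  format <- match.arg(format, c("gtf", "bed12"))
  empty_input <- !any(nzchar(readLines(path, warn = FALSE)))
  gr <- if (empty_input) GenomicRanges::GRanges()
        else if (format == "gtf") rtracklayer::import(path, format = "gtf")
        else rtracklayer::import(path, format = "bed")
  if (length(gr) == 0) {
    warning("no gene records in ", path)
    return(gene_set(character(), character(), character(),
                    numeric(), numeric()))
  }
  if (format == "gtf") return(genes_from_gtf(gr))
  genes_from_bed12(gr)
}

genes_from_gtf <- function(gr) {
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("unknown strand symbol '*' in GTF input")
  gid <- as.character(gr$gene_id)
  type <- tolower(as.character(gr$type))
  # 0-based half-open: GTF start is 1-based inclusive
  st <- GenomicRanges::start(gr) - 1
  en <- GenomicRanges::end(gr)
  ids <- unique(gid)
  exl <- vector("list", length(ids)); utl <- vector("list", length(ids))
  gs <- ge <- numeric(length(ids)); gc <- gstr <- character(length(ids))
  for (k in seq_along(ids)) {
    i <- which(gid == ids[k])
    gc[k] <- as.character(GenomicRanges::seqnames(gr))[i[1]]
    gstr[k] <- strand[i[1]]
    gs[k] <- min(st[i]); ge[k] <- max(en[i])
    ei <- i[type[i] == "exon"]
    exl[k] <- list(if (length(ei)) cbind(st[ei], en[ei]) else NULL)
    ui <- i[type[i] %in% c("five_prime_utr", "5utr")]
    utl[k] <- list(if (length(ui)) c(min(st[ui]), max(en[ui])) else NULL)
  }
  gene_set(ids, gc, gstr, gs, ge, exons = exl, utr5 = utl)
}

genes_from_bed12 <- function(gr) {
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("unknown strand symbol in BED12 input")
  blocks <- rtracklayer::blocks(gr)
  n <- length(gr)
  exl <- vector("list", n); utl <- vector("list", n)
  st <- GenomicRanges::start(gr) - 1
  en <- GenomicRanges::end(gr)
  thick <- gr$thick
  for (k in seq_len(n)) {
    b <- blocks[[k]]
    exl[[k]] <- cbind(GenomicRanges::start(b) - 1, GenomicRanges::end(b))
    if (!is.null(thick) && IRanges::width(thick)[k] > 0) {
      ts <- GenomicRanges::start(thick)[k] - 1
      te <- GenomicRanges::end(thick)[k]
      u <- if (strand[k] == "+") c(st[k], ts) else c(te, en[k])
      if (u[2] > u[1]) utl[[k]] <- u
    }
  }
  ids <- if (!is.null(gr$name)) as.character(gr$name)
         else sprintf("gene_%d", seq_len(n))
  gene_set(ids, as.character(GenomicRanges::seqnames(gr)), strand,
           st, en, exons = exl, utr5 = utl)
}

# Core promoter: the 5' UTR plus 1 kb upstream of the TSS (strand-oriented),
# as a single 0-based half-open interval per gene. Genes without an annotated
# 5' UTR use the TSS alone as the downstream edge.
core_promoter <- function(genes, upstream = 1000) {
  n <- nrow(genes)
  cs <- ce <- numeric(n)
  for (i in seq_len(n)) {
    u <- genes$utr5[[i]]
    if (genes$strand[i] == "+") {
      cs[i] <- max(0, genes$tss[i] - upstream)
      ce[i] <- if (!is.null(u)) max(genes$tss[i], u[2]) else genes$tss[i]
    } else {
      ce[i] <- genes$tss[i] + upstream
      cs[i] <- if (!is.null(u)) min(genes$tss[i], u[1]) else genes$tss[i]
    }
  }
  data.frame(chrom = genes$chrom, start = cs, end = ce,
             gene_id = genes$gene_id, stringsAsFactors = FALSE)
}
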