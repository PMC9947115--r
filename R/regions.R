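# Gene-panel regions and interval arithmetic, on GenomicRanges.

# Coerce region input to GRanges. Data frames are interpreted as
# BED-style 0-based half-open (chrom, start, end[, gene]); GRanges pass
# through unchanged (1-based inclusive, as usual in Bioconductor).
as_regions <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (any(x$end < x$start)) stop("intervals must have non-negative length")
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
  if ("gene" %in% names(x)) gr$name <- x$gene
  gr
}

#' Fraction of a panel overlapped by covered intervals
#'
#' Computes `sum(covered bases within panel) / sum(panel bases)`, the
#' standard panel-coverage ratio. Both arguments are reduced (merged)
#' before intersection, so overlapping input intervals are not counted
#' twice.
#'
#' @param covered covered intervals: a `GRanges` or a BED-style
#'   data.frame (`chrom`, 0-based `start`, `end`).
#' @param panel the panel regions, same representations.
#' @return a fraction in \[0, 1\].
#' @export
region_overlap <- function(covered, panel) {
  panel <- GenomicRanges::reduce(as_regions(panel), ignore.strand = TRUE)
  total <- sum(as.numeric(GenomicRanges::width(panel)))
  if (length(panel) == 0 || total == 0) stop("panel is empty")
  covered <- GenomicRanges::reduce(as_regions(covered), ignore.strand = TRUE)
  hit <- GenomicRanges::intersect(covered, panel, ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(hit))) / total
}

#' Read / write gene panels as BED
#'
#' Thin wrappers around [rtracklayer::import()] / `export()`; BED is
#' 0-based half-open on disk and 1-based inclusive as `GRanges` in
#' memory. Interval names (column 4) carry gene labels.
#'
#' @param path BED file path.
#' @return `read_panel_bed()`: a `GRanges` with a `name` metadata column.
#' @export
read_panel_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_panel_bed
#' @param panel a `GRanges` (gene labels in `name`).
#' @export
write_panel_bed <- function(panel, path) {
  rtracklayer::export(panel, path, format = "BED")
  invisible(path)
}

# GRanges of width-1 sites from a genotype table (optionally a subset).
site_ranges <- function(x, which = TRUE) {
  s <- x$sites[which, , drop = FALSE]
  GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, s$pos))
}
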