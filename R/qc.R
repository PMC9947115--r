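# Sequencing-quality metrics: allele dropout, genotype discordance,
# coverage, haplotypable genes, and the depth-gradient sweep.

# Accept a genotype vector or a genotype_table + sample role.
as_gt_vector <- function(x, sample) {
  if (inherits(x, "genotype_table")) get_gt(x, sample) else as.character(x)
}

#' Allele-dropout ratio of a single cell against a reference
#'
#' Fraction of sites at which the reference sample (amniotic
#' fluid/villi, or the simulated fetal truth) is heterozygous but the
#' single cell is called homozygous, among reference-heterozygous sites
#' with a non-missing cell call. Under per-allele dropout `d` alone the
#' expectation is `2d / (1 + d)` (see [expected_ado()]).
#'
#' @param cell,reference genotype vectors over the same sites, or
#'   [genotype_table()]s holding the respective samples.
#' @param cell_sample,reference_sample sample roles used when tables are
#'   passed.
#' @return the ratio, with attribute `n` (denominator); `NA` with `n = 0`
#'   when no site qualifies.
#' @export
ado_ratio <- function(cell, reference, cell_sample = "CELL",
                      reference_sample = "REFERENCE") {
  cg <- as_gt_vector(cell, cell_sample)
  rg <- as_gt_vector(reference, reference_sample)
  stopifnot(length(cg) == length(rg))
  den <- gt_is_het(rg) & !is.na(cg)
  num <- den & gt_is_hom(cg)
  out <- if (sum(den) == 0) NA_real_ else sum(num) / sum(den)
  structure(out, n = sum(den))
}

#' Genotype discordance (false-positive ratio) against a reference
#'
#' Fraction of sites with different genotypes in the cell and the
#' reference, among sites called in both. Any genotype difference
#' counts, so dropout-induced het-to-hom changes contribute; their share
#' is reported in the `n_ado_attributable` attribute so the
#' dropout-free discordance can be recomputed.
#'
#' @inheritParams ado_ratio
#' @return the ratio with attributes `n` (co-called sites) and
#'   `n_ado_attributable`; `NA` with `n = 0` when no site is co-called.
#' @export
false_positive_ratio <- function(cell, reference, cell_sample = "CELL",
                                 reference_sample = "REFERENCE") {
  cg <- as_gt_vector(cell, cell_sample)
  rg <- as_gt_vector(reference, reference_sample)
  stopifnot(length(cg) == length(rg))
  den <- !is.na(cg) & !is.na(rg)
  disc <- den & cg != rg
  ado_like <- disc & gt_is_het(rg) & gt_is_hom(cg)
  out <- if (sum(den) == 0) NA_real_ else sum(disc) / sum(den)
  structure(out, n = sum(den), n_ado_attributable = sum(ado_like))
}

#' Closed-form WGA artifact expectations and their inversion
#'
#' Under the observation model of [observe_single_cell()] with ample
#' depth, a truly heterozygous site is observed homozygous with
#' probability `(2d(1-e) + e) / (1+d)` where `d` is the per-allele
#' dropout rate and `e` the genotype-error rate (`2d/(1+d)` when
#' `e = 0`), and the overall discordance against a faithful reference is
#' `H * expected_ado(d, e) + (1-H) * e` where `H` is the heterozygous
#' fraction among co-called sites. `recover_wga_rates()` inverts the two
#' identities to estimate `(d, e)` from measured [ado_ratio()] and
#' [false_positive_ratio()].
#'
#' @param d per-allele dropout rate.
#' @param e per-site genotype-error rate.
#' @param het_fraction `H`, heterozygous fraction among co-called sites.
#' @return `expected_ado()`/`expected_fpr()`: a probability;
#'   `recover_wga_rates()`: named vector `c(d = , e = )`, clipped to
#'   \[0, 1\].
#' @export
expected_ado <- function(d, e = 0) (2 * d * (1 - e) + e) / (1 + d)

#' @rdname expected_ado
#' @export
expected_fpr <- function(d, e, het_fraction)
  het_fraction * expected_ado(d, e) + (1 - het_fraction) * e

#' @rdname expected_ado
#' @param ado,fpr measured ratios.
#' @export
recover_wga_rates <- function(ado, fpr, het_fraction) {
  e <- (fpr - het_fraction * ado) / (1 - het_fraction)
  e <- min(max(e, 0), 1)
  d <- (ado - e) / (2 - 2 * e - ado)
  d <- min(max(d, 0), 1)
  c(d = d, e = e)
}

#' Site-level genome coverage
#'
#' Fraction of sites at which a sample has at least one read — the
#' site-level surrogate for base-level genome coverage.
#'
#' @param table a [genotype_table()].
#' @param sample sample role.
#' @return fraction in \[0, 1\].
#' @export
genome_coverage <- function(table, sample = "CELL") {
  mean(get_dp(table, sample) >= 1)
}

#' Number of genes usable for haplotype analysis
#'
#' A gene is haplotypable when both its upstream and its downstream
#' flank contain at least one key SNP: strictly before the gene start
#' within `flank` bp, and strictly after the gene end within `flank` bp.
#'
#' @param genes gene intervals: `GRanges` (1-based) or data.frame with
#'   `chrom`, BED-style 0-based `start`, `end`.
#' @param key_snps key SNP positions: data.frame with `chrom`, `pos`, or
#'   a `GRanges` of width-1 sites.
#' @param flank flank width in bp (default 2 Mb, the window used around
#'   a disease locus).
#' @return integer count, with attribute `haplotypable` (per-gene logical).
#' @export
haplotypable_gene_count <- function(genes, key_snps, flank = 2e6) {
  if (flank <= 0) stop("flank must be positive")
  genes <- as_regions(genes)
  snps <- if (methods::is(key_snps, "GRanges")) key_snps
  else GenomicRanges::GRanges(key_snps$chrom,
                              IRanges::IRanges(key_snps$pos, key_snps$pos))
  up <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(start = pmax(1, GenomicRanges::start(genes) - flank + 1),
                     end = pmax(1, GenomicRanges::start(genes) - 1)))
  dn <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(start = GenomicRanges::end(genes) + 1,
                     end = GenomicRanges::end(genes) + flank - 1))
  ok <- GenomicRanges::countOverlaps(up, snps, ignore.strand = TRUE) >= 1 &
    GenomicRanges::countOverlaps(dn, snps, ignore.strand = TRUE) >= 1
  structure(sum(ok), haplotypable = ok)
}

#' Depth-gradient quality sweep
#'
#' Thins the cell's reads to each target depth and recomputes the QC
#' metrics, mimicking the subsampled-read evaluation of sequencing
#' depth. Thinning is coupled across the gradient (each depth is thinned
#' from the next higher one), so read counts — and hence site coverage —
#' are monotone in depth within a sweep while each gradient still has
#' the correct binomial marginal.
#'
#' @param table a [genotype_table()] whose `sample` was sequenced at
#'   (nominally) `source_depth`.
#' @param depths target mean depths, e.g. `c(1, 5, 10, 15, 20, 25, 30, 35)`.
#' @param sample,reference sample roles for the cell and its control.
#' @param source_depth nominal depth of the input sample; defaults to
#'   `max(depths)`.
#' @param panels optional named list of gene `GRanges`; adds per-panel
#'   site coverage and covered-gene counts.
#' @param seed integer seed for the thinning.
#' @param min_call_depth,min_alt_fraction caller thresholds.
#' @return data.frame with one row per gradient: `depth`, `mean_depth`
#'   (realised), `genome_coverage`, `ado_ratio`, `fp_ratio`, and per
#'   panel `<name>_coverage` / `<name>_genes_covered`.
#' @export
depth_gradient_analysis <- function(table,
                                    depths = c(1, 5, 10, 15, 20, 25, 30, 35),
                                    sample = "CELL", reference = "REFERENCE",
                                    source_depth = NULL,
                                    panels = NULL, seed = 1L,
                                    min_call_depth = 10,
                                    min_alt_fraction = 0.2) {
  stopifnot(inherits(table, "genotype_table"))
  if (is.null(source_depth)) source_depth <- max(depths)
  if (max(depths) > source_depth * (1 + 1e-9))
    stop("max(depths) exceeds source depth")
  ord <- order(depths, decreasing = TRUE)
  sr <- site_ranges(table)
  panel_hits <- lapply(panels, function(p)
    GenomicRanges::countOverlaps(sr, p, ignore.strand = TRUE) > 0)
  gene_of_site <- lapply(panels, function(p) {
    h <- GenomicRanges::findOverlaps(sr, p, ignore.strand = TRUE)
    h
  })

  cur <- table
  cur_depth <- source_depth
  rows <- vector("list", length(depths))
  for (k in seq_along(ord)) {
    dep <- depths[ord[k]]
    cur <- downsample_depth(cur, dep, sample = sample,
                            source_depth = cur_depth,
                            seed = as.integer(seed) + k,
                            min_call_depth = min_call_depth,
                            min_alt_fraction = min_alt_fraction)
    cur_depth <- dep
    dp <- get_dp(cur, sample)
    row <- data.frame(depth = dep,
                      mean_depth = mean(dp),
                      genome_coverage = mean(dp >= 1),
                      ado_ratio = as.numeric(ado_ratio(cur, cur,
                                                       cell_sample = sample,
                                                       reference_sample = reference)),
                      fp_ratio = as.numeric(false_positive_ratio(cur, cur,
                                                                 cell_sample = sample,
                                                                 reference_sample = reference)))
    for (pn in names(panels)) {
      inp <- panel_hits[[pn]]
      h <- gene_of_site[[pn]]
      covered_genes <- unique(S4Vectors::subjectHits(h)[dp[S4Vectors::queryHits(h)] >= 1])
      row[[paste0(pn, "_coverage")]] <- mean(dp[inp] >= 1)
      row[[paste0(pn, "_genes_covered")]] <- length(covered_genes)
    }
    rows[[ord[k]]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
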