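test_that("ADO and discordance ratios handle degenerate inputs", {
  ref <- c("0/1", "0/1", "0/0", "0/1", NA)
  expect_equal(as.numeric(ado_ratio(ref, ref)), 0)
  allhom <- c("0/0", "1/1", "0/0", "1/1", NA)
  expect_equal(as.numeric(ado_ratio(allhom, ref)), 1)
  expect_equal(as.numeric(false_positive_ratio(ref, ref)), 0)
  # 2 discordant of 20 co-called
  ref20 <- rep("0/0", 20)
  cell20 <- ref20; cell20[1:2] <- "0/1"
  expect_equal(as.numeric(false_positive_ratio(cell20, ref20)), 0.10)
  # no qualifying sites: NA with n = 0
  a <- ado_ratio(c("0/0", NA), c("0/0", "0/1"))
  expect_true(is.na(a))
  expect_identical(attr(a, "n"), 0L)
})

test_that("ratios agree with the site-by-site brute-force recount", {
  set.seed(99)
  states <- c("0/0", "0/1", "1/1", NA)
  for (rep in 1:10) {
    ref <- sample(states, 200, TRUE)
    cell <- sample(states, 200, TRUE)
    expect_equal(as.numeric(ado_ratio(cell, ref)), bf_ado(cell, ref))
    expect_equal(as.numeric(false_positive_ratio(cell, ref)),
                 bf_fpr(cell, ref))
  }
})

test_that("denominator bookkeeping partitions sites exactly", {
  set.seed(31)
  states <- c("0/0", "0/1", "1/1", NA)
  ref <- sample(states, 500, TRUE)
  cell <- sample(states, 500, TRUE)
  co <- !is.na(ref) & !is.na(cell)
  concord <- co & ref == cell
  discord <- co & ref != cell
  expect_identical(sum(concord) + sum(discord), sum(co))
  f <- false_positive_ratio(cell, ref)
  expect_identical(attr(f, "n"), sum(co))
  expect_equal(as.numeric(f) * attr(f, "n"), sum(discord))
  # reference-het sites split into het-preserved / hom-observed / missing
  rhet <- gt_is_het(ref)
  het_pres <- rhet & !is.na(cell) & cell == "0/1"
  hom_obs <- rhet & !is.na(cell) & gt_is_hom(cell)
  missing <- rhet & is.na(cell)
  expect_identical(sum(het_pres) + sum(hom_obs) + sum(missing), sum(rhet))
  a <- ado_ratio(cell, ref)
  expect_identical(attr(a, "n"), sum(het_pres) + sum(hom_obs))
})

test_that("injected dropout and error rates are recovered from the metrics", {
  d <- 0.1; e <- 0.03
  cfg <- sim_config(n_snps = 20000, seed = 61L, ado_rate = d, fp_rate = e,
                    mean_depth = 60)
  tab <- observe_single_cell(simulate_family(cfg))
  a <- ado_ratio(tab, tab); f <- false_positive_ratio(tab, tab)
  cg <- get_gt(tab, "CELL"); rg <- get_gt(tab, "REFERENCE")
  H <- mean(gt_is_het(rg)[!is.na(cg) & !is.na(rg)])
  hat <- recover_wga_rates(as.numeric(a), as.numeric(f), H)
  expect_lt(abs(hat[["d"]] - d), 0.015)
  expect_lt(abs(hat[["e"]] - e), 0.01)
  # forward closed forms agree within Monte-Carlo error
  pa <- expected_ado(d, e)
  expect_lt(abs(as.numeric(a) - pa),
            3 * sqrt(pa * (1 - pa) / attr(a, "n")))
  pf <- expected_fpr(d, e, H)
  expect_lt(abs(as.numeric(f) - pf),
            3 * sqrt(pf * (1 - pf) / attr(f, "n")))
})

test_that("haplotypable-gene rule needs a key SNP strictly on each side", {
  genes <- data.frame(chrom = "chr1", start = c(1000L, 5000L),
                      end = c(2000L, 6000L))       # 1-based inclusive
  flank <- 1500
  both <- data.frame(chrom = "chr1", pos = c(500L, 2500L, 4500L, 6500L))
  expect_identical(as.integer(haplotypable_gene_count(
    GenomicRanges::GRanges(genes$chrom,
                           IRanges::IRanges(genes$start, genes$end)),
    both, flank = flank)), 2L)
  none <- data.frame(chrom = "chr1", pos = c(1500L, 5500L))  # inside genes
  expect_identical(as.integer(haplotypable_gene_count(
    GenomicRanges::GRanges(genes$chrom,
                           IRanges::IRanges(genes$start, genes$end)),
    none, flank = flank)), 0L)
  expect_error(haplotypable_gene_count(genes, both, flank = 0), "positive")
})

test_that("haplotypable-gene count matches the per-gene brute-force scan", {
  set.seed(71)
  for (rep in 1:5) {
    genes <- data.frame(chrom = "chr1",
                        start = sort(sample(seq(1e4, 9e5, by = 1e4), 8)))
    genes$end <- genes$start + sample(2000:8000, 8)
    snps <- data.frame(chrom = "chr1", pos = sample(1:1e6, 60))
    flank <- sample(c(2e4, 5e4, 2e5), 1)
    gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
    expect_identical(as.integer(haplotypable_gene_count(gr, snps, flank)),
                     bf_haplotypable(genes, snps, flank))
  }
})

test_that("depth gradients report per-panel coverage and covered genes", {
  cfg <- quick_config(seed = 13L, mean_depth = 35, n_snps = 2000)
  tr <- simulate_family(cfg)
  tab <- observe_single_cell(tr)
  panel <- simulate_gene_panel(tr, n_genes = 20)
  grad <- depth_gradient_analysis(tab, depths = c(5, 15, 35),
                                  source_depth = 35,
                                  panels = list(panel = panel), seed = 2L)
  expect_identical(names(grad),
                   c("depth", "mean_depth", "genome_coverage", "ado_ratio",
                     "fp_ratio", "panel_coverage", "panel_genes_covered"))
  expect_true(all(diff(grad$panel_coverage) >= 0))
  expect_true(all(grad$panel_genes_covered <= 20))
  # the top gradient reproduces the undownsampled metrics
  expect_equal(grad$genome_coverage[3], genome_coverage(tab, "CELL"))
  expect_equal(grad$ado_ratio[3], as.numeric(ado_ratio(tab, tab)))
})
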