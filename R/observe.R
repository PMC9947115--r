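# Observation layer: bulk gDNA samples are read faithfully; the single
# cell passes through a WGA artifact model (per-allele dropout, genotype
# error, dispersed depth) before the depth-threshold caller.

# Deterministic read split for bulk gDNA: depth-limited missingness only,
# no stochastic allelic imbalance.
bulk_ad <- function(gt, depth) {
  n <- length(gt)
  ad_ref <- integer(n); ad_alt <- integer(n)
  het <- gt_is_het(gt)
  ad_ref[het] <- ceiling(depth[het] / 2)
  ad_alt[het] <- depth[het] - ad_ref[het]
  hom0 <- !is.na(gt) & gt %in% c("0/0", "0")
  hom1 <- !is.na(gt) & gt %in% c("1/1", "1")
  ad_ref[hom0] <- depth[hom0]
  ad_alt[hom1] <- depth[hom1]
  cbind(ref = ad_ref, alt = ad_alt)
}

#' Observe a family through sequencing, including a noisy single cell
#'
#' Produces the multi-sample [genotype_table()] the analysis consumes:
#' FATHER, MOTHER, PROBAND and REFERENCE (the fetal truth standing in
#' for an amniotic-fluid/villi control) are bulk gDNA samples with
#' Poisson depth and faithful genotypes; CELL is the fetal genome seen
#' through whole-genome amplification of a single cell. Per site the
#' cell model draws a depth with mean `mean_depth` (negative-binomial
#' with dispersion `depth_dispersion`, Poisson in the default limit),
#' drops each true allele independently with probability `ado_rate`,
#' replaces the surviving genotype with a uniformly chosen different one
#' with probability `fp_rate`, splits reads binomially between surviving
#' alleles, and calls genotypes with [call_genotype()]. Sites where both
#' alleles drop out yield no reads; sites at or below `min_call_depth`
#' are missing.
#'
#' @param truth a [simulate_family()] result.
#' @param config the matching [sim_config()] (defaults to the one stored
#'   in `truth`).
#' @return a [genotype_table()] with samples FATHER, MOTHER, PROBAND,
#'   REFERENCE, CELL.
#' @export
observe_single_cell <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "family_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  n <- nrow(truth$sites)
  tg <- true_genotypes(truth)
  x_linked <- truth$locus$inheritance_mode == "x_linked"
  male_fetus <- config$fetal_sex == "male"

  ploidy <- c(FATHER = if (x_linked) 1L else 2L,
              MOTHER = 2L,
              PROBAND = if (x_linked && config$proband_sex == "male") 1L else 2L,
              REFERENCE = if (x_linked && male_fetus) 1L else 2L,
              CELL = if (x_linked && male_fetus) 1L else 2L)

  gt <- matrix(NA_character_, n, 5,
               dimnames = list(NULL, names(ploidy)))
  ad_ref <- matrix(0L, n, 5, dimnames = dimnames(gt))
  ad_alt <- ad_ref

  for (s in c("FATHER", "MOTHER", "PROBAND", "REFERENCE")) {
    src <- if (s == "REFERENCE") "FETUS" else s
    depth <- rpois(n, config$gdna_depth)
    ad <- bulk_ad(tg[, src], depth)
    ad_ref[, s] <- ad[, "ref"]; ad_alt[, s] <- ad[, "alt"]
    gt[, s] <- call_genotype(ad[, "ref"], ad[, "alt"],
                             min_depth = config$min_call_depth,
                             min_alt_fraction = config$min_alt_fraction,
                             ploidy = ploidy[[s]])
  }

  # --- single cell ---
  alleles <- child_alleles(truth, "fetus")
  hemi <- ploidy[["CELL"]] == 1L
  d <- config$ado_rate
  keep1 <- runif(n) >= d
  keep2 <- if (hemi) rep(FALSE, n) else runif(n) >= d
  surv_gt <- rep(NA_character_, n)
  both <- keep1 & keep2
  surv_gt[both] <- gt_from_alleles(alleles[both, 1], alleles[both, 2])
  only1 <- keep1 & !keep2
  surv_gt[only1] <- if (hemi) as.character(alleles[only1, 1]) else
    gt_from_alleles(alleles[only1, 1], alleles[only1, 1])
  only2 <- !keep1 & keep2
  surv_gt[only2] <- gt_from_alleles(alleles[only2, 2], alleles[only2, 2])
  dropped <- is.na(surv_gt)

  # genotype error: replace the surviving genotype with a different one
  space <- if (hemi) GT_HEMI else GT_DIPLOID
  fp <- runif(n) < config$fp_rate & !dropped
  if (any(fp)) {
    i0 <- match(surv_gt[fp], space)
    off <- sample.int(length(space) - 1L, sum(fp), replace = TRUE)
    surv_gt[fp] <- space[((i0 - 1L + off) %% length(space)) + 1L]
  }

  depth <- if (is.finite(config$depth_dispersion))
    rnbinom(n, size = config$depth_dispersion, mu = config$mean_depth)
  else rpois(n, config$mean_depth)
  depth[dropped] <- 0L

  c_ref <- integer(n); c_alt <- integer(n)
  het <- gt_is_het(surv_gt)
  c_alt[het] <- rbinom(sum(het), depth[het], 0.5)
  c_ref[het] <- depth[het] - c_alt[het]
  hom0 <- !is.na(surv_gt) & surv_gt %in% c("0/0", "0")
  hom1 <- !is.na(surv_gt) & surv_gt %in% c("1/1", "1")
  c_ref[hom0] <- depth[hom0]
  c_alt[hom1] <- depth[hom1]
  ad_ref[, "CELL"] <- c_ref; ad_alt[, "CELL"] <- c_alt
  gt[, "CELL"] <- call_genotype(c_ref, c_alt,
                                min_depth = config$min_call_depth,
                                min_alt_fraction = config$min_alt_fraction,
                                ploidy = ploidy[["CELL"]])

  genotype_table(truth$sites[, c("chrom", "pos", "ref", "alt")],
                 gt, ad_ref, ad_alt, ploidy = ploidy)
}

#' Binomially thin a sample's reads to a lower depth
#'
#' Every read of the chosen sample is kept independently with
#' probability `target_depth / source_depth`, so the expected mean depth
#' after thinning equals `target_depth`; genotypes of that sample are
#' re-called with [call_genotype()]. A thinning fraction of exactly 1
#' returns the table unchanged.
#'
#' @param table a [genotype_table()].
#' @param target_depth desired mean depth; must not exceed `source_depth`.
#' @param sample which sample to thin (default `"CELL"`).
#' @param source_depth the depth the sample was sequenced at; defaults
#'   to its realised mean depth.
#' @param seed integer seed for the binomial thinning.
#' @param min_call_depth,min_alt_fraction caller thresholds for re-calling.
#' @return the table with the sample's depths and calls replaced.
#' @export
downsample_depth <- function(table, target_depth, sample = "CELL",
                             source_depth = NULL, seed = 1L,
                             min_call_depth = 10, min_alt_fraction = 0.2) {
  stopifnot(inherits(table, "genotype_table"))
  ad <- get_ad(table, sample)
  if (is.null(source_depth)) source_depth <- mean(ad[, "ref"] + ad[, "alt"])
  if (target_depth > source_depth * (1 + 1e-9))
    stop("target_depth (", target_depth, ") exceeds source depth (",
         round(source_depth, 3), ")")
  frac <- target_depth / source_depth
  if (frac >= 1) return(table)
  set.seed(as.integer(seed))
  new_ref <- rbinom(nrow(ad), ad[, "ref"], frac)
  new_alt <- rbinom(nrow(ad), ad[, "alt"], frac)
  gt <- call_genotype(new_ref, new_alt, min_depth = min_call_depth,
                      min_alt_fraction = min_alt_fraction,
                      ploidy = table$ploidy[[sample]])
  set_sample(table, sample, gt, new_ref, new_alt)
}

#' Simulate a gene panel inside the family's window
#'
#' Places non-overlapping gene intervals across the simulated region,
#' mimicking a targeted diagnostic panel (default 67 genes) for coverage
#' and haplotypability accounting.
#'
#' @param truth a [simulate_family()] result.
#' @param n_genes number of genes.
#' @param gene_length range of gene lengths in bp.
#' @param seed integer seed (defaults to the family seed).
#' @return a `GRanges` with a `name` metadata column.
#' @export
simulate_gene_panel <- function(truth, n_genes = 67,
                                gene_length = c(5e3, 5e4), seed = NULL) {
  stopifnot(inherits(truth, "family_truth"))
  if (is.null(seed)) seed <- truth$config$seed + 3000L
  set.seed(as.integer(seed))
  lo <- truth$window[["lo"]]; hi <- truth$window[["hi"]]
  slot <- (hi - lo) / n_genes
  len <- pmin(round(runif(n_genes, gene_length[1], gene_length[2])),
              floor(slot * 0.8))
  offset <- vapply(seq_len(n_genes), function(i)
    round(runif(1, 0, slot - len[i])), numeric(1))
  start <- round(lo + (seq_len(n_genes) - 1) * slot + offset)
  gr <- GenomicRanges::GRanges(
    truth$locus$chrom,
    IRanges::IRanges(start = start, end = start + len - 1))
  gr$name <- sprintf("GENE%03d", seq_len(n_genes))
  gr
}
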