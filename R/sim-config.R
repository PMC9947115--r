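#' Describe a pathogenic disease locus
#'
#' The anchor of the whole analysis: which gene and genomic position the
#' family's pathogenic variant(s) occupy, which parent(s) carry one, and
#' the inheritance mode. For compound-heterozygous families both parents
#' are carriers, each of a distinct variant near the same gene;
#' `carrier_positions` then holds one position per carrier (defaulting
#' to `position` for the father and `position + 500` for the mother so
#' the two variants are distinct sites, mirroring two different
#' pathogenic mutations in one gene).
#'
#' @param gene gene symbol (label only).
#' @param chrom chromosome of the locus.
#' @param position 1-based coordinate anchoring the flank windows.
#' @param carrier_parents subset of `c("father", "mother")` carrying a
#'   pathogenic variant (heterozygous).
#' @param inheritance_mode `"autosomal_recessive"`,
#'   `"autosomal_dominant"` or `"x_linked"`. X-linked loci must have the
#'   mother as the only carrier (a hemizygous affected father is out of
#'   scope).
#' @param carrier_positions optional named integer vector giving the
#'   pathogenic variant position per carrier parent.
#' @return an object of class `disease_locus`.
#' @examples
#' disease_locus("GJB2", "chr13", 20763612,
#'               carrier_parents = c("father", "mother"),
#'               inheritance_mode = "autosomal_recessive")
#' @export
disease_locus <- function(gene, chrom, position,
                          carrier_parents,
                          inheritance_mode = c("autosomal_recessive",
                                               "autosomal_dominant",
                                               "x_linked"),
                          carrier_positions = NULL) {
  inheritance_mode <- match.arg(inheritance_mode)
  carrier_parents <- match.arg(carrier_parents, c("father", "mother"),
                               several.ok = TRUE)
  position <- as.integer(position)
  if (position < 1) stop("position must be >= 1")
  if (inheritance_mode == "x_linked" && !identical(carrier_parents, "mother"))
    stop("configuration error: x_linked loci support only a maternal carrier")
  if (inheritance_mode == "autosomal_dominant" && length(carrier_parents) != 1)
    stop("autosomal_dominant loci take exactly one carrier parent")
  if (is.null(carrier_positions)) {
    carrier_positions <- setNames(
      position + ifelse(carrier_parents == "mother" &
                          "father" %in% carrier_parents, 500L, 0L),
      carrier_parents)
  }
  carrier_positions <- carrier_positions[carrier_parents]
  if (any(is.na(carrier_positions)))
    stop("carrier_positions must name every carrier parent")
  if (anyDuplicated(carrier_positions))
    stop("carrier parents must have distinct pathogenic positions")
  structure(list(gene = gene, chrom = chrom, position = position,
                 carrier_parents = carrier_parents,
                 inheritance_mode = inheritance_mode,
                 carrier_positions = carrier_positions),
            class = "disease_locus")
}

#' @export
print.disease_locus <- function(x, ...) {
  cat(sprintf("disease_locus %s (%s:%d), %s, carrier(s): %s\n",
              x$gene, x$chrom, x$position, x$inheritance_mode,
              paste(x$carrier_parents, collapse = " + ")))
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic family / single-cell
#' generator. Defaults reflect the study design the generator emulates:
#' a ~4 Mb window (2 Mb each side of the locus) holding ~6,000 SNPs (the
#' SNP yield observed in such windows at whole-genome depth), ~15x mean
#' single-cell sequencing depth with calls requiring depth > 10, and WGA
#' artifact rates of 0.2 per-allele dropout and 0.05 per-site genotype
#' error.
#'
#' @param n_snps number of background SNPs in the window (>= 10).
#' @param region_span window width in bp, centred on the disease locus.
#' @param maf_range range of the per-site minor (alternate) allele
#'   frequency, drawn uniformly.
#' @param mean_depth mean single-cell read depth per site.
#' @param depth_dispersion negative-binomial `size` for per-site depth;
#'   `Inf` (default) gives the Poisson limit, smaller values mimic WGA
#'   coverage non-uniformity.
#' @param ado_rate per-allele dropout probability in \[0, 1\].
#' @param fp_rate per-site probability that the post-dropout genotype is
#'   replaced by a different one (amplification/genotyping error).
#' @param min_call_depth calls require depth strictly greater than this.
#' @param min_alt_fraction heterozygous-call threshold, see
#'   [call_genotype()].
#' @param locus a [disease_locus()]; default: an autosomal-recessive
#'   compound-het deafness-gene locus with both parents carriers.
#' @param fetal_sex,proband_sex `"female"` or `"male"`. X-linked
#'   simulations require a male proband.
#' @param crossover_prob probability that a transmitted chromosome
#'   carries one crossover inside the window (breakpoint uniform); at
#'   most one crossover per meiosis is generated.
#' @param gdna_depth mean depth for bulk gDNA samples (parents, proband,
#'   reference).
#' @param fetal_locus_haps optional named vector, e.g.
#'   `c(paternal = 1, maternal = 2)`, forcing which parental haplotype
#'   the fetus inherits at the pathogenic locus; unset components are
#'   drawn at random.
#' @param seed integer seed (< 2^31 - 10^6); identical configurations
#'   give bit-identical simulations.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_snps = 6000, region_span = 4e6,
                       maf_range = c(0.05, 0.5),
                       mean_depth = 15, depth_dispersion = Inf,
                       ado_rate = 0.2, fp_rate = 0.05,
                       min_call_depth = 10, min_alt_fraction = 0.2,
                       locus = NULL,
                       fetal_sex = c("female", "male"),
                       proband_sex = c("male", "female"),
                       crossover_prob = 0.05,
                       gdna_depth = 30,
                       fetal_locus_haps = NULL,
                       seed = 1L) {
  fetal_sex <- match.arg(fetal_sex)
  proband_sex <- match.arg(proband_sex)
  if (is.null(locus))
    locus <- disease_locus("GJB2", "chr13", 20763612L,
                           carrier_parents = c("father", "mother"),
                           inheritance_mode = "autosomal_recessive")
  stopifnot(inherits(locus, "disease_locus"))
  if (n_snps < 10) stop("n_snps must be >= 10")
  if (region_span <= 0) stop("region_span must be positive")
  for (r in c(ado_rate, fp_rate, crossover_prob))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (mean_depth <= 0 || gdna_depth <= 0) stop("depths must be positive")
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) >= 2^31 - 1e6) stop("seed out of range")
  if (locus$inheritance_mode == "x_linked") {
    if (proband_sex != "male")
      stop("configuration error: x_linked simulations require a male proband")
  }
  if (!is.null(fetal_locus_haps)) {
    if (!all(names(fetal_locus_haps) %in% c("paternal", "maternal")) ||
        !all(fetal_locus_haps %in% 1:2))
      stop("fetal_locus_haps must be named paternal/maternal with values 1 or 2")
  }
  structure(list(n_snps = as.integer(n_snps),
                 region_span = as.integer(region_span),
                 maf_range = maf_range,
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 ado_rate = ado_rate, fp_rate = fp_rate,
                 min_call_depth = min_call_depth,
                 min_alt_fraction = min_alt_fraction,
                 locus = locus,
                 fetal_sex = fetal_sex, proband_sex = proband_sex,
                 crossover_prob = crossover_prob,
                 gdna_depth = gdna_depth,
                 fetal_locus_haps = fetal_locus_haps,
                 seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d SNPs over %.1f Mb around %s (%s)\n",
                     "  depth %g (gDNA %g), ADO %g, FP %g, seed %d\n"),
              x$n_snps, x$region_span / 1e6, x$locus$gene,
              x$locus$inheritance_mode, x$mean_depth, x$gdna_depth,
              x$ado_rate, x$fp_rate, x$seed))
  invisible(x)
}
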