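# Hand-built fixtures used across test files.

# Small multi-sample genotype table from named genotype vectors.
make_table <- function(..., pos = NULL, chrom = "chr1", ploidy = NULL,
                       ad_ref = NULL, ad_alt = NULL) {
  gt_list <- list(...)
  n <- length(gt_list[[1]])
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  sites <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  gt <- do.call(cbind, gt_list)
  genotype_table(sites, gt, ad_ref, ad_alt, ploidy = ploidy)
}

# Phased informative-SNP frame built directly (bypassing classification),
# for key-marking / voting / oracle tests.
make_phased <- function(pos, hap1_allele, shared = 0L, parent = "father",
                        chrom = "chr1", center = 100000L) {
  n <- length(pos)
  shared <- rep_len(as.integer(shared), n)
  df <- data.frame(chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G",
                   origin = ifelse(parent == "father", "IFF", "IFM"),
                   parent = parent,
                   shared_allele = shared,
                   distinguishing_allele = 1L - shared,
                   transmitted = NA_integer_,
                   distance = as.integer(pos) - as.integer(center),
                   hap1_allele = as.integer(hap1_allele),
                   proband_carries = TRUE,
                   stringsAsFactors = FALSE)
  class(df) <- c("informative_snps", "data.frame")
  df
}

# STR profile data.frame with a given number of detected loci.
make_str_profile <- function(n_detected, n_loci = 16,
                             allele1 = "10", allele2 = "12") {
  loci <- c(sprintf("L%02d", seq_len(n_loci - 1)), "AMEL")
  a1 <- rep(NA_character_, n_loci); a2 <- a1
  if (n_detected > 0) {
    a1[seq_len(n_detected)] <- allele1
    a2[seq_len(n_detected)] <- allele2
  }
  df <- data.frame(locus = loci, allele1 = a1, allele2 = a2,
                   stringsAsFactors = FALSE)
  attr(df, "panel") <- loci
  df
}

# A default small autosomal-recessive configuration for fast tests.
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(n_snps = 800, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}
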