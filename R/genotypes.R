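# Genotype calls are canonical VCF-style strings: "0/0", "0/1", "1/1" for
# diploid sites, "0" / "1" for hemizygous sites (male X), NA for missing.
# Only biallelic sites are handled; the alternate allele is always coded 1.

GT_DIPLOID <- c("0/0", "0/1", "1/1")
GT_HEMI <- c("0", "1")

#' Genotype state predicates
#'
#' Vectorised predicates over canonical genotype strings ("0/0", "0/1",
#' "1/1", "0", "1" or `NA` for missing). `gt_is_hom()` is true for
#' homozygous and hemizygous calls alike.
#'
#' @param gt character vector of genotype strings.
#' @return logical vector, `FALSE` for missing calls.
#' @export
gt_is_het <- function(gt) !is.na(gt) & gt == "0/1"

#' @rdname gt_is_het
#' @export
gt_is_hom <- function(gt) !is.na(gt) & gt %in% c("0/0", "1/1", GT_HEMI)

#' @rdname gt_is_het
#' @export
gt_is_hemi <- function(gt) !is.na(gt) & gt %in% GT_HEMI

#' Allele of a homozygous or hemizygous call
#'
#' @param gt character vector of genotype strings.
#' @return integer vector: 0, 1, or `NA` for heterozygous/missing calls.
#' @export
gt_hom_allele <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  out[!is.na(gt) & gt %in% c("0/0", "0")] <- 0L
  out[!is.na(gt) & gt %in% c("1/1", "1")] <- 1L
  out
}

#' Does a genotype contain a given allele?
#'
#' @param gt character vector of genotype strings.
#' @param allele 0 or 1 (recycled along `gt`).
#' @return logical vector, `FALSE` for missing calls.
#' @export
gt_contains <- function(gt, allele) {
  allele <- rep_len(as.character(allele), length(gt))
  ok <- !is.na(gt) & !is.na(allele)
  res <- logical(length(gt))
  res[ok] <- mapply(function(g, a) a %in% strsplit(g, "/", fixed = TRUE)[[1]],
                    gt[ok], allele[ok], USE.NAMES = FALSE)
  res
}

# Canonical genotype string from allele integers; b = NA gives a hemizygous call.
gt_from_alleles <- function(a, b = NA_integer_) {
  a <- as.integer(a)
  b <- rep_len(as.integer(b), length(a))
  out <- ifelse(is.na(b), as.character(a),
                paste(pmin(a, b), pmax(a, b), sep = "/"))
  out[is.na(a)] <- NA_character_
  out
}

#' Call a genotype from per-allele read depths
#'
#' Simple depth-threshold caller used throughout the package in place of
#' a read-level variant caller: a site is missing unless its total depth
#' strictly exceeds `min_depth`; a diploid site is heterozygous when both
#' alleles carry at least `min_alt_fraction` of the reads, otherwise
#' homozygous for the majority allele. Hemizygous sites (ploidy 1) take
#' the majority allele.
#'
#' @param ad_ref,ad_alt integer vectors of reference / alternate read counts.
#' @param min_depth sites with total depth `<= min_depth` are missing
#'   (strict ">" threshold; default 10).
#' @param min_alt_fraction minimum fraction of reads per allele for a
#'   heterozygous call (default 0.2).
#' @param ploidy 1 or 2, recycled along sites.
#' @return character vector of genotype strings (`NA` = missing).
#' @examples
#' call_genotype(c(8, 20, 12), c(2, 0, 12))
#' @export
call_genotype <- function(ad_ref, ad_alt, min_depth = 10,
                          min_alt_fraction = 0.2, ploidy = 2L) {
  stopifnot(length(ad_ref) == length(ad_alt))
  if (any(ad_ref < 0, na.rm = TRUE) || any(ad_alt < 0, na.rm = TRUE))
    stop("allele depths must be non-negative")
  n <- length(ad_ref)
  ploidy <- rep_len(as.integer(ploidy), n)
  total <- ad_ref + ad_alt
  gt <- rep(NA_character_, n)
  called <- !is.na(total) & total > min_depth

  dip <- called & ploidy == 2L
  het <- dip & ad_ref >= min_alt_fraction * total & ad_alt >= min_alt_fraction * total
  gt[het] <- "0/1"
  gt[dip & !het & ad_ref >= ad_alt] <- "0/0"
  gt[dip & !het & ad_ref < ad_alt] <- "1/1"

  hemi <- called & ploidy == 1L
  gt[hemi & ad_ref >= ad_alt] <- "0"
  gt[hemi & ad_ref < ad_alt] <- "1"
  gt
}
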