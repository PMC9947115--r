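#' Multi-sample genotype table
#'
#' The central container of the package: an ordered list of biallelic
#' SNP sites together with one genotype call and one pair of per-allele
#' read depths per (site, sample). Samples are identified by role names
#' such as `"FATHER"`, `"MOTHER"`, `"PROBAND"`, `"CELL"` and
#' `"REFERENCE"` (an amniotic-fluid or villi control, or the simulated
#' fetal truth).
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; one row per site, ordered by position.
#' @param gt character matrix of genotype strings, sites x samples, with
#'   sample names as column names.
#' @param ad_ref,ad_alt integer matrices of per-allele read depths with
#'   the same shape as `gt` (default all zero).
#' @param ploidy named integer vector, ploidy per sample (default 2).
#' @return an object of class `genotype_table`.
#' @seealso [read_family_vcf()], [write_family_vcf()], [observe_single_cell()]
#' @export
genotype_table <- function(sites, gt, ad_ref = NULL, ad_alt = NULL,
                           ploidy = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  gt <- as.matrix(gt)
  if (is.null(colnames(gt))) stop("gt must have sample names as colnames")
  if (nrow(gt) != nrow(sites)) stop("gt rows must match sites")
  if (any(sites$pos < 1)) stop("positions must be >= 1")
  bad <- !is.na(gt) & !(gt %in% c(GT_DIPLOID, GT_HEMI))
  if (any(bad)) stop("invalid genotype strings: ", paste(unique(gt[bad]), collapse = ", "))
  zero <- matrix(0L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  if (is.null(ad_ref)) ad_ref <- zero
  if (is.null(ad_alt)) ad_alt <- zero
  ad_ref <- as.matrix(ad_ref); ad_alt <- as.matrix(ad_alt)
  storage.mode(ad_ref) <- "integer"; storage.mode(ad_alt) <- "integer"
  if (!identical(dim(ad_ref), dim(gt)) || !identical(dim(ad_alt), dim(gt)))
    stop("allele-depth matrices must match gt")
  if (any(ad_ref < 0) || any(ad_alt < 0)) stop("depths must be >= 0")
  if (is.null(ploidy)) ploidy <- setNames(rep(2L, ncol(gt)), colnames(gt))
  ploidy <- ploidy[colnames(gt)]
  if (any(is.na(ploidy))) stop("ploidy must be named per sample")
  sites$pos <- as.integer(sites$pos)
  rownames(sites) <- NULL
  structure(list(sites = sites, gt = gt, ad_ref = ad_ref, ad_alt = ad_alt,
                 ploidy = ploidy),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$sites), "sites x", ncol(x$gt), "samples (",
      paste(colnames(x$gt), collapse = ", "), ")\n")
  ncall <- colSums(!is.na(x$gt))
  cat("  called per sample:", paste(sprintf("%s=%d", names(ncall), ncall),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Accessors for genotype tables
#'
#' `get_gt()` returns the genotype-string vector of one sample,
#' `get_ad()` a two-column (ref, alt) depth matrix, `get_dp()` the total
#' depth, and `gt_samples()` the sample roles present.
#'
#' @param x a [genotype_table()].
#' @param sample sample role name.
#' @export
get_gt <- function(x, sample) {
  stopifnot(inherits(x, "genotype_table"))
  if (!sample %in% colnames(x$gt)) stop("no sample '", sample, "' in table")
  x$gt[, sample]
}

#' @rdname get_gt
#' @export
get_ad <- function(x, sample) {
  stopifnot(inherits(x, "genotype_table"))
  if (!sample %in% colnames(x$gt)) stop("no sample '", sample, "' in table")
  cbind(ref = x$ad_ref[, sample], alt = x$ad_alt[, sample])
}

#' @rdname get_gt
#' @export
get_dp <- function(x, sample) {
  ad <- get_ad(x, sample)
  ad[, "ref"] + ad[, "alt"]
}

#' @rdname get_gt
#' @export
gt_samples <- function(x) colnames(x$gt)

# Replace one sample's depths and calls, returning a new table.
set_sample <- function(x, sample, gt, ad_ref, ad_alt) {
  x$gt[, sample] <- gt
  x$ad_ref[, sample] <- as.integer(ad_ref)
  x$ad_alt[, sample] <- as.integer(ad_alt)
  x
}

# Row indices of (chrom, pos) pairs in a table; NA where absent.
match_sites <- function(x, chrom, pos) {
  match(paste(chrom, pos), paste(x$sites$chrom, x$sites$pos))
}
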