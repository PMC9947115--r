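# VCF v4.2 import/export of the multi-sample genotype matrix, via vcfR.

#' Read a family VCF into a genotype table
#'
#' Reads a multi-sample VCF (plain or bgzip/gzip compressed) and returns
#' a [genotype_table()] restricted to biallelic SNP records. Records that
#' are multiallelic or non-SNP are skipped and counted in the
#' `"n_excluded"` attribute. Half-calls (e.g. `./1`) and `./.` are
#' treated as missing; phased separators are normalised to unphased.
#'
#' @param path path to a VCF file with GT (and optionally AD) FORMAT fields.
#' @param sample_roles named character vector mapping sample roles to VCF
#'   sample names, e.g. `c(FATHER = "F01", MOTHER = "M01", ...)`. The
#'   default expects samples already named by role and requires at least
#'   FATHER, MOTHER and PROBAND.
#' @return a [genotype_table()] whose columns are the names of
#'   `sample_roles`, with attribute `n_excluded`.
#' @export
read_family_vcf <- function(path,
                            sample_roles = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) stop("no variant records in ", path)
  snp <- vcfR::is.biallelic(v) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_excluded <- sum(!snp)
  if (n_excluded > 0)
    message("read_family_vcf: skipped ", n_excluded,
            " multiallelic or non-SNP record(s)")
  v <- v[snp, ]
  fix <- v@fix

  vcf_samples <- colnames(v@gt)[-1]
  if (is.null(sample_roles)) {
    known <- intersect(vcf_samples,
                       c("FATHER", "MOTHER", "PROBAND", "CELL", "REFERENCE"))
    sample_roles <- setNames(known, known)
    need <- c("FATHER", "MOTHER", "PROBAND")
    if (!all(need %in% names(sample_roles)))
      stop("missing sample role(s): ",
           paste(setdiff(need, names(sample_roles)), collapse = ", "))
  }
  absent <- setdiff(sample_roles, vcf_samples)
  if (length(absent) > 0)
    stop("sample(s) not in VCF: ", paste(absent, collapse = ", "))

  gtm <- vcfR::extract.gt(v, element = "GT")
  gtm <- gtm[, sample_roles, drop = FALSE]
  colnames(gtm) <- names(sample_roles)
  gtm <- gsub("|", "/", gtm, fixed = TRUE)
  norm <- function(g) {
    out <- rep(NA_character_, length(g))
    ok <- !is.na(g)
    parts <- strsplit(g[ok], "/", fixed = TRUE)
    out[ok] <- vapply(parts, function(p) {
      if (any(p == ".")) return(NA_character_)
      if (length(p) == 1) return(p)
      paste(sort(p), collapse = "/")
    }, character(1))
    out
  }
  gtm <- apply(gtm, 2, norm)

  adm <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                  error = function(e) NULL)
  n <- nrow(fix)
  zero <- matrix(0L, n, ncol(gtm), dimnames = dimnames(gtm))
  ad_ref <- zero; ad_alt <- zero
  if (!is.null(adm)) {
    adm <- adm[, sample_roles, drop = FALSE]
    colnames(adm) <- names(sample_roles)
    for (s in colnames(adm)) {
      parts <- strsplit(ifelse(is.na(adm[, s]), "0,0", adm[, s]), ",", fixed = TRUE)
      ad_ref[, s] <- as.integer(vapply(parts, `[`, character(1), 1))
      ad_alt[, s] <- as.integer(vapply(parts, function(p)
        if (length(p) >= 2) p[2] else "0", character(1)))
    }
  }
  ploidy <- setNames(
    ifelse(apply(gtm, 2, function(g) any(gt_is_hemi(g))), 1L, 2L),
    colnames(gtm))

  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  out <- genotype_table(sites, gtm, ad_ref, ad_alt, ploidy = ploidy)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write a genotype table as a multi-sample VCF
#'
#' Emits VCF v4.2 with GT, DP and AD FORMAT fields. Output is
#' gzip-compressed; a `.gz` suffix is appended if absent.
#'
#' @param x a [genotype_table()].
#' @param path output path (will end in `.vcf.gz`).
#' @return the path written, invisibly.
#' @export
write_family_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_table"))
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  n <- nrow(x$sites)
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=cellhap",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")
  fix <- cbind(CHROM = x$sites$chrom, POS = as.character(x$sites$pos),
               ID = rep(".", n), REF = x$sites$ref, ALT = x$sites$alt,
               QUAL = rep(".", n), FILTER = rep(".", n), INFO = rep(".", n))
  fmt <- function(s) {
    g <- x$gt[, s]
    g[is.na(g)] <- ifelse(x$ploidy[[s]] == 1L, ".", "./.")
    dp <- x$ad_ref[, s] + x$ad_alt[, s]
    paste0(g, ":", dp, ":", x$ad_ref[, s], ",", x$ad_alt[, s])
  }
  gt <- cbind(FORMAT = rep("GT:DP:AD", n),
              vapply(colnames(x$gt), fmt, character(n)))
  colnames(gt) <- c("FORMAT", colnames(x$gt))
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Export genotype calls as TSV
#'
#' One row per site with chrom, pos, ref, alt and per-sample genotype and
#' depth columns.
#'
#' @param x a [genotype_table()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genotype_tsv <- function(x, path) {
  df <- x$sites
  for (s in colnames(x$gt)) {
    df[[paste0(s, "_gt")]] <- x$gt[, s]
    df[[paste0(s, "_dp")]] <- x$ad_ref[, s] + x$ad_alt[, s]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
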