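# STR profiles and fetal-origin confirmation. A profile is a data.frame
# (locus, allele1, allele2) over a fixed panel; the default 16-locus
# panel mirrors a forensic identity kit: 13 core CODIS loci, D2S1338,
# D19S433, and the amelogenin sex marker.

STR_PANEL_16 <- c("D8S1179", "D21S11", "D7S820", "CSF1PO", "D3S1358",
                  "TH01", "D13S317", "D16S539", "D2S1338", "D19S433",
                  "vWA", "TPOX", "D18S51", "D5S818", "FGA", "AMEL")

str_profile <- function(locus, allele1, allele2, panel = locus) {
  df <- data.frame(locus = locus, allele1 = as.character(allele1),
                   allele2 = as.character(allele2), stringsAsFactors = FALSE)
  if (!all(df$locus %in% panel)) stop("loci outside the declared panel")
  attr(df, "panel") <- panel
  class(df) <- c("str_profile", "data.frame")
  df
}

str_panel <- function(x) {
  p <- attr(x, "panel")
  if (is.null(p)) x$locus else p
}

#' Simulate STR profiles for father, mother and a single fetal cell
#'
#' Draws multiallelic repeat alleles per locus for both parents, lets
#' the cell inherit one paternal and one maternal allele, and hides each
#' cell locus independently with probability `1 - detection_rate`
#' (emulating allele dropout / PCR failure of single-cell WGA products;
#' parental gDNA profiles are always complete). The amelogenin marker is
#' modelled as X/Y with the cell's alleles set by fetal sex.
#'
#' @param truth a [simulate_family()] result (supplies fetal sex and the
#'   default seed).
#' @param n_loci panel size (default 16, amelogenin included as the last
#'   locus).
#' @param detection_rate per-locus probability that the cell's locus is
#'   detected.
#' @param seed integer seed (defaults to the family seed).
#' @return list with elements `father`, `mother`, `cell`, each an
#'   `str_profile` data.frame (locus, allele1, allele2; `NA` alleles =
#'   locus not detected).
#' @export
simulate_str_profiles <- function(truth, n_loci = 16, detection_rate = 0.75,
                                  seed = NULL) {
  stopifnot(inherits(truth, "family_truth"))
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (detection_rate < 0 || detection_rate > 1)
    stop("detection_rate must lie in [0, 1]")
  if (is.null(seed)) seed <- truth$config$seed + 2000L
  set.seed(as.integer(seed))
  loci <- if (n_loci == 16) STR_PANEL_16
  else c(sprintf("STR%02d", seq_len(n_loci - 1)), "AMEL")
  n_auto <- length(loci) - 1L

  draw <- function() matrix(as.character(sample(6:20, 2 * n_auto, replace = TRUE)),
                            ncol = 2)
  fa <- draw(); mo <- draw()
  pick <- function(m) m[cbind(seq_len(n_auto), sample.int(2L, n_auto, TRUE))]
  cell_a <- pick(fa); cell_b <- pick(mo)

  male <- truth$config$fetal_sex == "male"
  father <- str_profile(loci, c(fa[, 1], "X"), c(fa[, 2], "Y"), panel = loci)
  mother <- str_profile(loci, c(mo[, 1], "X"), c(mo[, 2], "X"), panel = loci)
  cell <- str_profile(loci, c(cell_a, if (male) "Y" else "X"),
                      c(cell_b, "X"), panel = loci)
  undetected <- runif(length(loci)) >= detection_rate
  cell$allele1[undetected] <- NA_character_
  cell$allele2[undetected] <- NA_character_
  list(father = father, mother = mother, cell = cell)
}

#' STR locus detection rate of a cell profile
#'
#' @param cell an `str_profile` (or data.frame with columns `locus`,
#'   `allele1`, `allele2`).
#' @return percentage of panel loci with at least one detected allele,
#'   e.g. 75 for 12 of 16.
#' @export
str_detection_rate <- function(cell) {
  panel <- str_panel(cell)
  if (length(panel) < 1) stop("empty STR panel")
  detected <- !is.na(cell$allele1) | !is.na(cell$allele2)
  100 * sum(detected) / length(panel)
}

#' Paternal-specific STR alleles in a candidate fetal cell
#'
#' An allele counts as paternal-specific at a locus when it is present
#' in both the cell and the father and absent from the mother there.
#' Undetected cell loci contribute nothing. The amelogenin sex marker is
#' excluded from scoring by default (it is not a polymorphic repeat);
#' cell alleles found in neither parent are reported separately as
#' unattributed rather than counted.
#'
#' @param cell,father,mother `str_profile`s over a shared panel.
#' @param exclude_loci loci excluded from scoring (default `"AMEL"`).
#' @return list with `per_locus` (named list of paternal-specific
#'   alleles), `count` (total), and `unattributed` (cell alleles absent
#'   from both parents).
#' @export
paternal_specific_alleles <- function(cell, father, mother,
                                      exclude_loci = "AMEL") {
  loci <- setdiff(intersect(cell$locus, intersect(father$locus, mother$locus)),
                  exclude_loci)
  per_locus <- list()
  unattributed <- list()
  for (l in loci) {
    ca <- stats::na.omit(unlist(cell[cell$locus == l, c("allele1", "allele2")]))
    if (length(ca) == 0) next
    fa <- stats::na.omit(unlist(father[father$locus == l, c("allele1", "allele2")]))
    ma <- stats::na.omit(unlist(mother[mother$locus == l, c("allele1", "allele2")]))
    spec <- unique(ca[ca %in% fa & !(ca %in% ma)])
    if (length(spec) > 0) per_locus[[l]] <- unname(spec)
    orphan <- unique(ca[!(ca %in% fa) & !(ca %in% ma)])
    if (length(orphan) > 0) unattributed[[l]] <- unname(orphan)
  }
  list(per_locus = per_locus,
       count = length(unlist(per_locus)),
       unattributed = unattributed)
}

#' Score a candidate cell as fetal from paternal-specific alleles
#'
#' Cells showing multiple paternal-specific alleles are scored as fetal
#' (circulating trophoblasts); "multiple" defaults to at least 2.
#'
#' @param paternal_allele_count total from [paternal_specific_alleles()].
#' @param threshold minimum count to confirm (>= 1).
#' @return `TRUE` if the cell is confirmed fetal.
#' @export
classify_fetal_origin <- function(paternal_allele_count, threshold = 2) {
  if (threshold < 1) stop("threshold must be >= 1")
  paternal_allele_count >= threshold
}

#' Read / write STR profiles as TSV
#'
#' Long format with columns `locus`, `sample`, `allele1`, `allele2`.
#'
#' @param profiles named list of `str_profile`s.
#' @param path file path.
#' @return `read_str_profiles()`: a named list of `str_profile`s.
#' @export
write_str_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(names(profiles), function(s) {
    p <- profiles[[s]]
    data.frame(locus = p$locus, sample = s,
               allele1 = p$allele1, allele2 = p$allele2,
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_str_profiles
#' @export
read_str_profiles <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = c("NA", ""))
  out <- lapply(split(df, df$sample), function(d)
    str_profile(d$locus, d$allele1, d$allele2, panel = unique(df$locus)))
  out
}
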