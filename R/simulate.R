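# Synthetic family generator: parental haplotypes, meioses with at most
# one crossover, pathogenic variants planted per inheritance mode.

# One transmitted chromosome: start haplotype uniform, with probability
# xo_prob one crossover at a uniform breakpoint. Anchoring at a site
# relabels (swaps) the whole vector, which preserves the distribution of
# crossover count and breakpoint.
draw_transmission <- function(pos, lo, hi, xo_prob,
                              anchor_idx = NULL, anchor_hap = NULL) {
  n <- length(pos)
  start <- sample.int(2L, 1L)
  t <- rep(start, n)
  if (runif(1) < xo_prob) {
    b <- runif(1, lo, hi)
    t[pos >= b] <- 3L - start
  }
  if (!is.null(anchor_idx) && t[anchor_idx] != anchor_hap) t <- 3L - t
  t
}

#' Simulate a family with known haplotypes
#'
#' Draws biallelic SNPs around the disease locus, four parental
#' haplotypes (two for an X-linked father), plants the pathogenic
#' variant(s) on haplotype 1 of each carrier parent, and simulates the
#' proband's and fetus's meioses with at most one crossover per
#' transmitted chromosome. The proband always inherits the pathogenic
#' haplotype(s) (it is the affected child anchoring the phasing); the
#' fetal transmissions are random unless forced via
#' `fetal_locus_haps` in the configuration.
#'
#' Parental haplotype 1 is by construction the haplotype carrying that
#' parent's pathogenic allele (P1 / M1); haplotype 2 is the wild-type
#' one (P2 / M2).
#'
#' @param config a [sim_config()].
#' @return an object of class `family_truth`: site table (including the
#'   pathogenic site(s)), parental haplotype matrices, per-site
#'   transmission vectors for proband and fetus, the resolved locus and
#'   the configuration.
#' @seealso [observe_single_cell()], [true_genotypes()]
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  locus <- config$locus
  x_linked <- locus$inheritance_mode == "x_linked"
  span <- config$region_span
  center <- locus$position
  lo <- max(1L, center - span %/% 2L)
  hi <- lo + span
  path_pos <- locus$carrier_positions
  if (any(path_pos < lo | path_pos > hi))
    stop("pathogenic position(s) outside the simulated window")

  raw <- lo - 1L + sort(sample.int(span + 1L, config$n_snps + 8L))
  raw <- setdiff(raw, path_pos)
  pos <- raw[seq_len(config$n_snps)]

  maf <- runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, config$n_snps, replace = TRUE)
  alt_choices <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                        nrow = 4, byrow = TRUE,
                        dimnames = list(bases, NULL))
  alt <- alt_choices[cbind(match(ref, bases),
                           sample.int(3L, config$n_snps, replace = TRUE))]

  sites <- data.frame(chrom = locus$chrom, pos = pos, ref = ref, alt = alt,
                      maf = maf, pathogenic = FALSE,
                      pathogenic_parent = NA_character_,
                      stringsAsFactors = FALSE)
  path_sites <- data.frame(chrom = locus$chrom, pos = unname(path_pos),
                           ref = "C", alt = "T", maf = 0,
                           pathogenic = TRUE,
                           pathogenic_parent = names(path_pos),
                           stringsAsFactors = FALSE)
  sites <- rbind(sites, path_sites)
  sites <- sites[order(sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  n <- nrow(sites)
  path_idx <- setNames(match(path_pos, sites$pos), names(path_pos))

  draw_haps <- function(k) {
    m <- matrix(0L, nrow = k, ncol = n)
    for (h in seq_len(k)) m[h, ] <- rbinom(n, 1L, sites$maf)
    m
  }
  father <- draw_haps(if (x_linked) 1L else 2L)
  mother <- draw_haps(2L)
  # plant pathogenic alleles: carrier haplotype 1 carries the alt allele
  for (pc in locus$carrier_parents) {
    i <- path_idx[[pc]]
    if (pc == "father") { father[1L, i] <- 1L; father[2L, i] <- 0L }
    else { mother[1L, i] <- 1L; mother[2L, i] <- 0L }
    if (pc == "father") mother[, i] <- 0L else father[, i] <- 0L
  }

  draw_child <- function(sex, anchors) {
    pat <- if (x_linked) {
      if (sex == "male") NULL else rep(1L, n)   # father's X passes intact
    } else {
      a <- anchors[["paternal"]]
      draw_transmission(sites$pos, lo, hi, config$crossover_prob,
                        anchor_idx = if (!is.null(a)) path_idx[["father"]],
                        anchor_hap = a)
    }
    a <- anchors[["maternal"]]
    mat <- draw_transmission(sites$pos, lo, hi, config$crossover_prob,
                             anchor_idx = if (!is.null(a)) path_idx[["mother"]],
                             anchor_hap = a)
    list(paternal = pat, maternal = mat)
  }
  proband_anchor <- list(
    paternal = if ("father" %in% locus$carrier_parents) 1L else NULL,
    maternal = if ("mother" %in% locus$carrier_parents) 1L else NULL)
  fetal_anchor <- list(
    paternal = if (!is.null(config$fetal_locus_haps) &&
                   "paternal" %in% names(config$fetal_locus_haps) &&
                   "father" %in% locus$carrier_parents)
      as.integer(config$fetal_locus_haps[["paternal"]]) else NULL,
    maternal = if (!is.null(config$fetal_locus_haps) &&
                   "maternal" %in% names(config$fetal_locus_haps) &&
                   "mother" %in% locus$carrier_parents)
      as.integer(config$fetal_locus_haps[["maternal"]]) else NULL)

  proband <- draw_child(config$proband_sex, proband_anchor)
  fetus <- draw_child(config$fetal_sex, fetal_anchor)

  locus$carrier_positions <- path_pos
  structure(list(sites = sites,
                 father_haps = father, mother_haps = mother,
                 transmissions = list(proband = proband, fetus = fetus),
                 path_idx = path_idx,
                 window = c(lo = lo, hi = hi),
                 locus = locus, config = config),
            class = "family_truth")
}

#' @export
print.family_truth <- function(x, ...) {
  cat(sprintf("family_truth: %d sites on %s, %s at %s, fetal %s\n",
              nrow(x$sites), x$locus$chrom, x$locus$inheritance_mode,
              x$locus$gene, x$config$fetal_sex))
  th <- true_fetal_haplotypes(x)
  cat("  fetal haplotypes at locus:",
      paste(sprintf("%s=%s", names(th), th), collapse = ", "), "\n")
  invisible(x)
}

# Allele pair transmitted to a child; b is NA for a hemizygous genome.
child_alleles <- function(truth, who = c("proband", "fetus")) {
  who <- match.arg(who)
  tr <- truth$transmissions[[who]]
  n <- nrow(truth$sites)
  idx <- seq_len(n)
  a_mat <- truth$mother_haps[cbind(tr$maternal, idx)]
  if (is.null(tr$paternal))
    return(cbind(a1 = a_mat, a2 = rep(NA_integer_, n)))
  cbind(a1 = truth$father_haps[cbind(tr$paternal, idx)], a2 = a_mat)
}

#' True genotypes of all family members
#'
#' @param truth a [simulate_family()] result.
#' @return character matrix of genotype strings with columns FATHER,
#'   MOTHER, PROBAND, FETUS.
#' @export
true_genotypes <- function(truth) {
  stopifnot(inherits(truth, "family_truth"))
  f <- if (nrow(truth$father_haps) == 1L)
    as.character(truth$father_haps[1L, ])
  else gt_from_alleles(truth$father_haps[1L, ], truth$father_haps[2L, ])
  m <- gt_from_alleles(truth$mother_haps[1L, ], truth$mother_haps[2L, ])
  pa <- child_alleles(truth, "proband")
  fa <- child_alleles(truth, "fetus")
  cbind(FATHER = f, MOTHER = m,
        PROBAND = gt_from_alleles(pa[, 1], pa[, 2]),
        FETUS = gt_from_alleles(fa[, 1], fa[, 2]))
}

#' Which parental haplotypes the fetus inherited at the locus
#'
#' The simulation's ground truth for the diagnostic question: haplotype
#' label (1 = pathogenic-carrying, 2 = wild-type) transmitted to the
#' fetus at each carrier parent's pathogenic site.
#'
#' @param truth a [simulate_family()] result.
#' @return named integer vector with elements `paternal` and/or
#'   `maternal` (only carrier parents are reported).
#' @export
true_fetal_haplotypes <- function(truth) {
  stopifnot(inherits(truth, "family_truth"))
  tr <- truth$transmissions$fetus
  out <- integer(0)
  if ("father" %in% truth$locus$carrier_parents && !is.null(tr$paternal))
    out <- c(out, paternal = tr$paternal[truth$path_idx[["father"]]])
  if ("mother" %in% truth$locus$carrier_parents)
    out <- c(out, maternal = tr$maternal[truth$path_idx[["mother"]]])
  out
}
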