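# Analytical core: informative-SNP classification, proband-anchored
# phasing, key-SNP marking, flank-wise voting and the diagnostic verdict.

#' Classify informative SNPs from the trio
#'
#' A site inside the flank window is an informative SNP from the father
#' (IFF) when the father is heterozygous and the mother homozygous (or
#' hemizygous), and an informative SNP from the mother (IFM) in the
#' mirrored case; both parents and the proband must be called, and the
#' proband's genotype must permit unambiguous inference of the allele
#' the informative parent transmitted (the homozygous parent's allele is
#' subtracted from the proband genotype). Sites where both parents are
#' heterozygous are dropped, as are the pathogenic site(s) themselves
#' and Mendelian-inconsistent sites (counted in the
#' `n_inconsistent` attribute).
#'
#' @param table a [genotype_table()] with FATHER, MOTHER, PROBAND.
#' @param locus a [disease_locus()].
#' @param flank window half-width in bp around the locus (default 2 Mb).
#' @return a data.frame of class `informative_snps`: one row per
#'   informative SNP with `chrom`, `pos`, `ref`, `alt`, `origin`
#'   (IFF/IFM), `parent`, `shared_allele` (the homozygous parent's
#'   allele), `distinguishing_allele`, `transmitted` (allele the
#'   informative parent passed to the proband) and `distance` (signed bp
#'   from the locus, negative = upstream).
#' @export
classify_informative_snps <- function(table, locus, flank = 2e6) {
  stopifnot(inherits(table, "genotype_table"), inherits(locus, "disease_locus"))
  s <- table$sites
  f <- get_gt(table, "FATHER")
  m <- get_gt(table, "MOTHER")
  p <- get_gt(table, "PROBAND")

  in_win <- s$chrom == locus$chrom &
    abs(s$pos - locus$position) <= flank &
    !(s$pos %in% locus$carrier_positions)
  iff <- in_win & gt_is_het(f) & gt_is_hom(m) & !is.na(p)
  ifm <- in_win & gt_is_het(m) & gt_is_hom(f) & !is.na(p)

  n_bad <- 0L
  infer <- function(idx, origin) {
    if (!any(idx)) return(NULL)
    shared <- if (origin == "IFF") gt_hom_allele(m[idx]) else gt_hom_allele(f[idx])
    pg <- p[idx]
    hemi_p <- gt_is_hemi(pg)
    transmitted <- rep(NA_integer_, sum(idx))
    if (origin == "IFM") {
      # a hemizygous proband's single allele is the maternal transmission
      transmitted[hemi_p] <- gt_hom_allele(pg[hemi_p])
    }
    dip <- !hemi_p
    het_p <- gt_is_het(pg) & dip
    transmitted[het_p] <- 1L - shared[het_p]
    hom_p <- gt_is_hom(pg) & dip
    hom_a <- gt_hom_allele(pg)
    consistent_hom <- hom_p & hom_a == shared
    transmitted[consistent_hom] <- shared[consistent_hom]
    # hom for the non-shared allele is Mendelian-inconsistent: drop
    keep <- !is.na(transmitted)
    n_bad <<- n_bad + sum(!keep)
    data.frame(chrom = s$chrom[idx][keep], pos = s$pos[idx][keep],
               ref = s$ref[idx][keep], alt = s$alt[idx][keep],
               origin = origin,
               parent = if (origin == "IFF") "father" else "mother",
               shared_allele = shared[keep],
               distinguishing_allele = 1L - shared[keep],
               transmitted = transmitted[keep],
               distance = s$pos[idx][keep] - locus$position,
               stringsAsFactors = FALSE)
  }
  out <- rbind(infer(iff, "IFF"), infer(ifm, "IFM"))
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), origin = character(),
                      parent = character(), shared_allele = integer(),
                      distinguishing_allele = integer(),
                      transmitted = integer(), distance = integer(),
                      stringsAsFactors = FALSE)
  } else {
    out <- out[order(out$pos), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("informative_snps", "data.frame")
  attr(out, "n_inconsistent") <- n_bad
  out
}

#' Phase informative SNPs onto the pathogenic parental haplotype
#'
#' For each carrier parent, resolves from the proband's genotype at that
#' parent's pathogenic site whether the proband inherited the pathogenic
#' haplotype; if so, each allele that parent transmitted to the proband
#' is placed on haplotype 1 (the pathogenic-carrying P1/M1), otherwise
#' on haplotype 2. No recombination is assumed inside the flank window
#' (a proband crossover there is undetectable with a single proband and
#' simply propagates; the simulation modules quantify the induced
#' error).
#'
#' @param informative result of [classify_informative_snps()].
#' @param table the trio [genotype_table()].
#' @param locus the [disease_locus()]; the pathogenic allele is the ALT
#'   allele at each carrier position.
#' @return `informative` with columns `hap1_allele` (allele on the
#'   pathogenic haplotype; `NA` for SNPs of non-carrier origin) and
#'   `proband_carries` added.
#' @export
phase_to_pathogenic <- function(informative, table, locus) {
  stopifnot(inherits(informative, "informative_snps"),
            inherits(table, "genotype_table"))
  informative$hap1_allele <- NA_integer_
  informative$proband_carries <- NA
  for (pc in locus$carrier_parents) {
    ppos <- locus$carrier_positions[[pc]]
    i <- match_sites(table, locus$chrom, ppos)
    if (is.na(i))
      stop("phasing error: pathogenic site ", locus$chrom, ":", ppos,
           " absent from the genotype table")
    pg <- get_gt(table, "PROBAND")[i]
    if (is.na(pg))
      stop("phasing error: proband genotype missing at the pathogenic locus")
    cg <- get_gt(table, if (pc == "father") "FATHER" else "MOTHER")[i]
    if (!gt_is_het(cg))
      stop("phasing error: carrier parent (", pc,
           ") is not heterozygous at its pathogenic site")
    og <- get_gt(table, if (pc == "father") "MOTHER" else "FATHER")[i]
    if (!is.na(og) && gt_contains(og, 1L))
      stop("phasing error: pathogenic allele cannot be attributed to the ",
           pc, " (other parent also carries it)")
    carries <- gt_contains(pg, 1L)
    rows <- informative$parent == pc
    informative$hap1_allele[rows] <-
      if (carries) informative$transmitted[rows]
      else 1L - informative$transmitted[rows]
    informative$proband_carries[rows] <- carries
  }
  informative
}

#' Mark key SNPs against the observed cell genotype
#'
#' A phased informative SNP is a key SNP when the cell's observation
#' cannot be explained away by a single allele dropout under the
#' competing transmission hypothesis: operationally, when the observed
#' genotype contains the distinguishing allele (the informative parent's
#' allele absent from the homozygous parent). Observations homozygous
#' for the shared allele are compatible with either transmission once
#' dropout is allowed, and missing observations carry no information;
#' both are non-key. For a hemizygous cell (male X) every called site is
#' key, since the single observed allele is the maternal transmission
#' itself. Each key SNP votes for the parental haplotype that carries
#' its identified allele.
#'
#' `mode = "het_only"` is a stricter variant in which only heterozygous
#' cell observations are key: a homozygous-distinguishing observation
#' still identifies the transmission but is itself dropout-affected.
#'
#' @param phased result of [phase_to_pathogenic()].
#' @param table a [genotype_table()] containing the cell.
#' @param cell_sample cell sample role.
#' @param mode `"observation"` (default) or `"het_only"`.
#' @return `phased` with columns `cell_gt`, `key` and `vote_hap`
#'   (1, 2 or `NA`) added.
#' @export
mark_key_snps <- function(phased, table, cell_sample = "CELL",
                          mode = c("observation", "het_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(phased, "informative_snps"))
  idx <- match_sites(table, phased$chrom, phased$pos)
  if (any(is.na(idx))) stop("informative SNPs missing from the cell table")
  cg <- get_gt(table, cell_sample)[idx]
  hemi <- gt_is_hemi(cg)

  key <- logical(nrow(phased))
  vote_allele <- rep(NA_integer_, nrow(phased))

  has_dist <- gt_contains(cg, phased$distinguishing_allele) & !hemi
  if (mode == "het_only") has_dist <- has_dist & gt_is_het(cg)
  key[has_dist] <- TRUE
  vote_allele[has_dist] <- phased$distinguishing_allele[has_dist]

  # male-X cell: the single called allele is the maternal transmission
  key[hemi] <- TRUE
  vote_allele[hemi] <- gt_hom_allele(cg[hemi])

  phased$cell_gt <- cg
  phased$key <- key
  phased$vote_hap <- ifelse(key & !is.na(phased$hap1_allele),
                            ifelse(vote_allele == phased$hap1_allele, 1L, 2L),
                            NA_integer_)
  phased
}

flank_decision <- function(n1, n2, vote_threshold, min_key) {
  total <- n1 + n2
  if (total < min_key)
    return(list(label = NA_integer_,
                reason = sprintf("only %d key SNP(s), need %d", total, min_key)))
  win <- if (n1 >= n2) 1L else 2L
  frac <- max(n1, n2) / total
  if (frac < vote_threshold)
    return(list(label = NA_integer_,
                reason = sprintf("vote fraction %.2f below threshold %.2f",
                                 frac, vote_threshold)))
  list(label = win, reason = NULL)
}

#' Call the fetal haplotype inherited from one parent
#'
#' Key SNPs vote for parental haplotype 1 (pathogenic-carrying) or 2 in
#' each flank; a flank decides when it holds at least
#' `min_key_per_flank` key votes and the majority reaches
#' `vote_threshold`. The call is the common flank decision; discordant
#' flanks suggest a fetal recombination inside the window and yield an
#' ambiguous call with `recombination_flag` set rather than a forced
#' label.
#'
#' @param phased result of [mark_key_snps()].
#' @param parent `"paternal"` or `"maternal"` (also accepts
#'   `"father"`/`"mother"`).
#' @param vote_threshold minimum winning vote fraction per flank
#'   (default 0.8).
#' @param min_key_per_flank minimum key votes per flank (default 1).
#' @return an object of class `haplotype_call`: `parent`, `label` ("1",
#'   "2" or "ambiguous"), per-flank vote counts `up_votes` / `down_votes`
#'   (named `hap1`, `hap2`), `recombination_flag` and a diagnostic
#'   `message` when ambiguous.
#' @export
call_fetal_haplotype <- function(phased, parent,
                                 vote_threshold = 0.8,
                                 min_key_per_flank = 1L) {
  stopifnot(inherits(phased, "informative_snps"))
  parent_name <- switch(parent,
                        paternal = , father = "father",
                        maternal = , mother = "mother",
                        stop("parent must be paternal or maternal"))
  rows <- phased$parent == parent_name & phased$key & !is.na(phased$vote_hap)
  up <- rows & phased$distance < 0
  dn <- rows & phased$distance > 0
  uv <- c(hap1 = sum(phased$vote_hap[up] == 1L),
          hap2 = sum(phased$vote_hap[up] == 2L))
  dv <- c(hap1 = sum(phased$vote_hap[dn] == 1L),
          hap2 = sum(phased$vote_hap[dn] == 2L))
  u <- flank_decision(uv[["hap1"]], uv[["hap2"]], vote_threshold, min_key_per_flank)
  d <- flank_decision(dv[["hap1"]], dv[["hap2"]], vote_threshold, min_key_per_flank)

  label <- "ambiguous"; recomb <- FALSE; msg <- NULL
  if (!is.na(u$label) && !is.na(d$label)) {
    if (u$label == d$label) label <- as.character(u$label)
    else {
      recomb <- TRUE
      msg <- sprintf("flank discordance (upstream hap%d, downstream hap%d): possible fetal recombination",
                     u$label, d$label)
    }
  } else {
    msg <- paste(c(if (is.na(u$label)) paste("upstream:", u$reason),
                   if (is.na(d$label)) paste("downstream:", d$reason)),
                 collapse = "; ")
  }
  structure(list(parent = switch(parent_name, father = "paternal",
                                 mother = "maternal"),
                 label = label,
                 up_votes = uv, down_votes = dv,
                 recombination_flag = recomb,
                 vote_threshold = vote_threshold,
                 min_key_per_flank = as.integer(min_key_per_flank),
                 message = msg),
            class = "haplotype_call")
}

#' @export
print.haplotype_call <- function(x, ...) {
  cat(sprintf("%s haplotype call: %s (upstream %d/%d, downstream %d/%d for hap1/hap2)\n",
              x$parent, x$label,
              x$up_votes[["hap1"]], x$up_votes[["hap2"]],
              x$down_votes[["hap1"]], x$down_votes[["hap2"]]))
  if (x$recombination_flag) cat("  recombination flag set\n")
  if (!is.null(x$message) && nzchar(x$message)) cat(" ", x$message, "\n")
  invisible(x)
}

# Verdict from haplotype labels; labels are "1", "2" or "ambiguous"
# (NULL = no call needed/possible for that parent).
verdict_from_labels <- function(pat, mat, locus, fetal_sex) {
  mode <- locus$inheritance_mode
  amb <- function(x) !is.null(x) && x == "ambiguous"
  if (mode == "x_linked") {
    if (is.null(mat)) stop("missing required maternal call")
    if (amb(mat)) return("ambiguous")
    if (fetal_sex == "male")
      return(if (mat == "1") "affected" else "normal")
    return(if (mat == "1") "carrier_maternal" else "normal")
  }
  carriers <- locus$carrier_parents
  need_pat <- "father" %in% carriers
  need_mat <- "mother" %in% carriers
  if (need_pat && is.null(pat)) stop("missing required paternal call")
  if (need_mat && is.null(mat)) stop("missing required maternal call")
  if ((need_pat && amb(pat)) || (need_mat && amb(mat))) return("ambiguous")
  if (mode == "autosomal_dominant") {
    lab <- if (need_pat) pat else mat
    return(if (lab == "1") "affected" else "normal")
  }
  # autosomal recessive
  if (need_pat && need_mat) {
    if (pat == "1" && mat == "1") return("affected")
    if (pat == "1") return("carrier_paternal")
    if (mat == "1") return("carrier_maternal")
    return("normal")
  }
  if (need_pat) return(if (pat == "1") "carrier_paternal" else "normal")
  if (mat == "1") "carrier_maternal" else "normal"
}

#' Map fetal haplotype calls to a diagnostic verdict
#'
#' For an autosomal-recessive locus with both parents carriers the four
#' haplotype combinations map to: P1/M1 affected, P1/M2 carrier from
#' father, P2/M1 carrier from mother, P2/M2 normal. For an X-linked
#' locus only the maternal haplotype matters: a male fetus is affected
#' with M1 and normal with M2 (a female is a carrier with M1). Dominant
#' loci map the carrier parent's haplotype 1 to affected. Any ambiguous
#' required call yields an ambiguous verdict.
#'
#' @param paternal,maternal [call_fetal_haplotype()] results (or `NULL`
#'   where no call is applicable, e.g. paternal for an X-linked male).
#' @param locus the [disease_locus()].
#' @param fetal_sex `"female"` or `"male"`.
#' @return an object of class `verdict`: `value` (one of affected,
#'   carrier_paternal, carrier_maternal, normal, ambiguous) and `basis`
#'   (the input calls).
#' @export
derive_verdict <- function(paternal = NULL, maternal = NULL, locus,
                           fetal_sex = c("female", "male")) {
  fetal_sex <- match.arg(fetal_sex)
  stopifnot(inherits(locus, "disease_locus"))
  lab <- function(x) {
    if (is.null(x)) return(NULL)
    stopifnot(inherits(x, "haplotype_call"))
    x$label
  }
  value <- verdict_from_labels(lab(paternal), lab(maternal), locus, fetal_sex)
  structure(list(value = value,
                 basis = list(paternal = paternal, maternal = maternal),
                 inheritance_mode = locus$inheritance_mode,
                 fetal_sex = fetal_sex),
            class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  labs <- vapply(x$basis, function(b) if (is.null(b)) "-" else b$label,
                 character(1))
  cat(sprintf("verdict: %s (paternal %s / maternal %s, %s, fetal sex %s)\n",
              x$value, labs[["paternal"]], labs[["maternal"]],
              x$inheritance_mode, x$fetal_sex))
  invisible(x)
}
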