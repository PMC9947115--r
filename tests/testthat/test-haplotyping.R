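# Locus used by the hand-built trio fixtures: paternal carrier at chr1:5000.
fixture_locus <- function(carriers = "father",
                          mode = "autosomal_recessive") {
  disease_locus("GENE1", "chr1", 5000L, carrier_parents = carriers,
                inheritance_mode = mode,
                carrier_positions = setNames(
                  c(5000L, 5500L)[seq_along(carriers)], carriers))
}

test_that("informative SNPs require one het parent, one hom parent, and a proband call", {
  tab <- make_table(
    FATHER  = c("0/1", "0/1", "0/0", "0/1", "0/1", "1/1", "0/1"),
    MOTHER  = c("0/0", "0/1", "0/1", "1/1", "0/0", "0/1", "0/0"),
    PROBAND = c("0/1", "0/1", "0/1", "0/1", NA,    "1/1", "1/1"),
    pos = c(1000L, 2000L, 3000L, 4000L, 6000L, 7000L, 8000L))
  inf <- classify_informative_snps(tab, fixture_locus())
  # site 1: IFF; site 2: both het, dropped; site 3: IFM; site 4: IFF with
  # mother 1/1; site 5: proband missing; site 6: IFM; site 7: IFF but
  # proband 1/1 is Mendelian-inconsistent with mother 0/0
  expect_identical(inf$origin, c("IFF", "IFM", "IFF", "IFM"))
  expect_identical(inf$pos, c(1000L, 3000L, 4000L, 7000L))
  expect_identical(attr(inf, "n_inconsistent"), 1L)
  # transmitted allele is the proband allele left after subtracting the
  # homozygous parent's contribution
  expect_identical(inf$transmitted, c(1L, 1L, 0L, 1L))
  expect_identical(inf$distance, inf$pos - 5000L)
})

test_that("phasing assigns transmitted alleles to P1 when the proband carries the variant", {
  pos <- c(1000L, 3000L, 5000L, 7000L)
  base <- list(
    FATHER  = c("0/1", "0/1", "0/1", "0/1"),
    MOTHER  = c("0/0", "1/1", "0/0", "0/0"),
    PROBAND = c("0/1", "0/1", "0/1", "0/0"))
  tab <- do.call(make_table, c(base, list(pos = pos)))
  locus <- fixture_locus()
  inf <- classify_informative_snps(tab, locus)
  ph <- phase_to_pathogenic(inf, tab, locus)
  # proband carries the paternal variant (0/1 at 5000): transmitted -> P1
  expect_identical(ph$pos, c(1000L, 3000L, 7000L))
  expect_identical(ph$hap1_allele, c(1L, 0L, 0L))
  expect_true(all(ph$proband_carries))
  # proband without the variant: the complement lies on P1
  base$PROBAND[3] <- "0/0"
  tab2 <- do.call(make_table, c(base, list(pos = pos)))
  ph2 <- phase_to_pathogenic(classify_informative_snps(tab2, locus), tab2, locus)
  expect_identical(ph2$hap1_allele, c(0L, 1L, 1L))
  # missing proband genotype at the locus is a phasing error
  base$PROBAND[3] <- NA
  tab3 <- do.call(make_table, c(base, list(pos = pos)))
  expect_error(phase_to_pathogenic(classify_informative_snps(tab3, locus),
                                   tab3, locus), "phasing error")
})

test_that("phased alleles equal the true pathogenic haplotype in a clean family", {
  cfg <- quick_config(seed = 14L, ado_rate = 0, fp_rate = 0,
                      mean_depth = 40, crossover_prob = 0)
  tr <- simulate_family(cfg)
  tab <- observe_single_cell(tr)
  ph <- phase_to_pathogenic(classify_informative_snps(tab, tr$locus),
                            tab, tr$locus)
  idx <- match(ph$pos, tr$sites$pos)
  pat <- ph$parent == "father"
  expect_identical(ph$hap1_allele[pat], unname(tr$father_haps[1, idx[pat]]))
  expect_identical(ph$hap1_allele[!pat], unname(tr$mother_haps[1, idx[!pat]]))
})

test_that("key SNPs are exactly the observations showing the distinguishing allele", {
  # IFF sites, mother 0/0 (shared 0, distinguishing 1), hap1 carries 1
  ph <- make_phased(pos = c(1000L, 2000L, 3000L, 4000L),
                    hap1_allele = 1L, shared = 0L, center = 2500L)
  tab <- make_table(CELL = c("0/1", "1/1", "0/0", NA),
                    pos = c(1000L, 2000L, 3000L, 4000L))
  keyed <- mark_key_snps(ph, tab)
  expect_identical(keyed$key, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(keyed$vote_hap, c(1L, 1L, NA, NA))
  # under the stricter mode only the het observation is key
  strict <- mark_key_snps(ph, tab, mode = "het_only")
  expect_identical(strict$key, c(TRUE, FALSE, FALSE, FALSE))
  # when hap1 carries the shared allele, the same observations vote hap2
  ph2 <- make_phased(pos = c(1000L, 2000L), hap1_allele = 0L, shared = 0L,
                     center = 2500L)
  tab2 <- make_table(CELL = c("0/1", "1/1"), pos = c(1000L, 2000L))
  expect_identical(mark_key_snps(ph2, tab2)$vote_hap, c(2L, 2L))
})

test_that("hemizygous cell observations are always key and vote their allele", {
  ph <- make_phased(pos = c(1000L, 2000L, 3000L), hap1_allele = c(1L, 1L, 1L),
                    shared = 0L, parent = "mother", center = 1500L)
  tab <- make_table(CELL = c("1", "0", NA), pos = c(1000L, 2000L, 3000L),
                    ploidy = c(CELL = 1L))
  keyed <- mark_key_snps(ph, tab)
  expect_identical(keyed$key, c(TRUE, TRUE, FALSE))
  expect_identical(keyed$vote_hap, c(1L, 2L, NA))
})

test_that("flank-wise voting reproduces counted calls and flags discordance", {
  mk <- function(up1, up2, dn1, dn2) {
    n <- up1 + up2 + dn1 + dn2
    pos <- c(seq_len(up1 + up2) * 10L, 1000L + seq_len(dn1 + dn2) * 10L)
    ph <- make_phased(pos = pos, hap1_allele = 1L, shared = 0L, center = 900L)
    votes <- c(rep("0/1", up1), rep("0/0", up2),
               rep("0/1", dn1), rep("0/0", dn2))
    # hap2 votes need the distinguishing allele on hap2: flip hap1_allele
    flip <- c(rep(FALSE, up1), rep(TRUE, up2), rep(FALSE, dn1), rep(TRUE, dn2))
    ph$hap1_allele[flip] <- 0L
    votes[flip] <- "0/1"
    tab <- make_table(CELL = votes, pos = pos)
    call_fetal_haplotype(mark_key_snps(ph, tab), "paternal")
  }
  # the headline structure: 10 upstream and 3 downstream key SNPs for hap 1
  call <- mk(10, 0, 3, 0)
  expect_identical(call$label, "1")
  expect_identical(call$up_votes, c(hap1 = 10L, hap2 = 0L))
  expect_identical(call$down_votes, c(hap1 = 3L, hap2 = 0L))
  expect_false(call$recombination_flag)
  # unanimous but opposite flanks: ambiguous with the recombination flag
  disc <- mk(6, 0, 0, 5)
  expect_identical(disc$label, "ambiguous")
  expect_true(disc$recombination_flag)
  # an empty flank cannot support a call
  onesided <- mk(8, 0, 0, 0)
  expect_identical(onesided$label, "ambiguous")
  expect_match(onesided$message, "downstream")
  # below the vote-fraction threshold the flank abstains
  weak <- mk(3, 2, 4, 0)
  expect_identical(weak$label, "ambiguous")
  expect_match(weak$message, "vote fraction")
})

test_that("verdicts map haplotype combinations exactly", {
  loc2 <- fixture_locus(c("father", "mother"))
  fake_call <- function(parent, label) {
    structure(list(parent = parent, label = label,
                   up_votes = c(hap1 = 1L, hap2 = 0L),
                   down_votes = c(hap1 = 1L, hap2 = 0L),
                   recombination_flag = FALSE, message = NULL),
              class = "haplotype_call")
  }
  v <- function(p, m) derive_verdict(fake_call("paternal", p),
                                     fake_call("maternal", m), loc2)$value
  expect_identical(v("1", "1"), "affected")
  expect_identical(v("1", "2"), "carrier_paternal")
  expect_identical(v("2", "1"), "carrier_maternal")
  expect_identical(v("2", "2"), "normal")
  expect_identical(v("ambiguous", "1"), "ambiguous")
  expect_error(derive_verdict(fake_call("paternal", "1"), NULL, loc2),
               "missing required maternal")
  # X-linked male: only the maternal haplotype matters
  xl <- disease_locus("F9", "chrX", 5000L, carrier_parents = "mother",
                      inheritance_mode = "x_linked")
  expect_identical(derive_verdict(NULL, fake_call("maternal", "1"), xl,
                                  fetal_sex = "male")$value, "affected")
  expect_identical(derive_verdict(NULL, fake_call("maternal", "2"), xl,
                                  fetal_sex = "male")$value, "normal")
  expect_identical(derive_verdict(NULL, fake_call("maternal", "1"), xl,
                                  fetal_sex = "female")$value,
                   "carrier_maternal")
  # dominant: the carrier parent's pathogenic haplotype means affected
  ad <- fixture_locus("father", mode = "autosomal_dominant")
  expect_identical(derive_verdict(fake_call("paternal", "1"), NULL, ad)$value,
                   "affected")
  expect_identical(derive_verdict(fake_call("paternal", "2"), NULL, ad)$value,
                   "normal")
})

test_that("swapping the pathogenic haplotype flips labels but not vote counts", {
  cfg <- quick_config(seed = 23L, crossover_prob = 0)
  tr <- simulate_family(cfg)
  tab <- observe_single_cell(tr)
  locus <- tr$locus
  inf <- classify_informative_snps(tab, locus)
  run <- function(t) {
    keyed <- mark_key_snps(phase_to_pathogenic(inf, t, locus), t)
    call_fetal_haplotype(keyed, "paternal")
  }
  c1 <- run(tab)
  # flip the proband's genotype at the paternal pathogenic site: the same
  # physical haplotype is now labelled 2 instead of 1
  i <- which(tab$sites$pos == locus$carrier_positions[["father"]])
  tab2 <- tab
  tab2$gt[i, "PROBAND"] <- if (gt_contains(tab$gt[i, "PROBAND"], 1)) "0/0" else "0/1"
  c2 <- run(tab2)
  expect_identical(c1$up_votes[["hap1"]], c2$up_votes[["hap2"]])
  expect_identical(c1$up_votes[["hap2"]], c2$up_votes[["hap1"]])
  expect_identical(c1$down_votes[["hap1"]], c2$down_votes[["hap2"]])
  if (c1$label %in% c("1", "2"))
    expect_identical(c2$label, c(`1` = "2", `2` = "1")[[c1$label]])
})

test_that("without noise every transmitted distinguishing allele is key and calls match truth", {
  for (seed in c(3L, 4L)) {
    cfg <- quick_config(seed = seed, ado_rate = 0, fp_rate = 0,
                        mean_depth = 40, crossover_prob = 0)
    tr <- simulate_family(cfg)
    tab <- observe_single_cell(tr)
    keyed <- mark_key_snps(phase_to_pathogenic(
      classify_informative_snps(tab, tr$locus), tab, tr$locus), tab)
    truth <- true_fetal_haplotypes(tr)
    cg <- get_gt(tab, "CELL")
    idx <- match(keyed$pos, tab$sites$pos)
    called <- !is.na(cg[idx])
    # which haplotype the fetus actually received from the informative parent
    fet <- ifelse(keyed$parent == "father",
                  tr$transmissions$fetus$paternal[idx],
                  tr$transmissions$fetus$maternal[idx])
    hap_allele <- ifelse(fet == 1L, keyed$hap1_allele, 1L - keyed$hap1_allele)
    transmitted_dist <- hap_allele == keyed$distinguishing_allele
    expect_identical(keyed$key[called], transmitted_dist[called])
    for (p in c("paternal", "maternal")) {
      call <- call_fetal_haplotype(keyed, p)
      lab <- as.character(truth[[p]])
      expect_identical(call$label, lab)
      loser <- paste0("hap", c(`1` = "2", `2` = "1")[[lab]])
      expect_identical(call$up_votes[[loser]], 0L)
      expect_identical(call$down_votes[[loser]], 0L)
    }
  }
})

test_that("the voting caller agrees with the exhaustive dropout oracle", {
  set.seed(404)
  n_checked <- 0L
  for (rep in 1:400) {
    n <- sample(2:12, 1)
    pos <- sort(sample(c(-(1:2000), 1:2000), n)) + 100000L
    ph <- make_phased(pos = pos, hap1_allele = sample(0:1, n, TRUE),
                      shared = sample(0:1, n, TRUE), center = 100000L)
    obs <- sample(c("0/0", "0/1", "1/1", NA), n, TRUE,
                  prob = c(0.3, 0.3, 0.2, 0.2))
    tab <- make_table(CELL = obs, pos = pos)
    keyed <- mark_key_snps(ph, tab)
    oracle <- oracle_haplotype(ph, obs)
    call <- call_fetal_haplotype(keyed, "paternal")
    if (oracle$decisive && call$label != "ambiguous") {
      expect_identical(call$label, as.character(oracle$label))
      n_checked <- n_checked + 1L
    }
    if (oracle$decisive &&
        sum(keyed$key & keyed$distance < 0) >= 1 &&
        sum(keyed$key & keyed$distance > 0) >= 1) {
      # votes in both flanks plus a decisive oracle force a concordant call
      expect_identical(call$label, as.character(oracle$label))
    }
  }
  expect_gt(n_checked, 20)
})

test_that("noise increases ambiguity and does not break unambiguous accuracy", {
  run_one <- function(seed, d, e, xo = 0) {
    cfg <- quick_config(seed = seed, ado_rate = d, fp_rate = e, n_snps = 600,
                        crossover_prob = xo)
    tr <- simulate_family(cfg)
    tab <- observe_single_cell(tr)
    keyed <- mark_key_snps(phase_to_pathogenic(
      classify_informative_snps(tab, tr$locus), tab, tr$locus), tab)
    truth <- true_fetal_haplotypes(tr)
    out <- c(amb = 0L, err = 0L, n = 0L)
    for (p in c("paternal", "maternal")) {
      call <- call_fetal_haplotype(keyed, p, min_key_per_flank = 3L)
      out["n"] <- out["n"] + 1L
      if (call$label == "ambiguous") out["amb"] <- out["amb"] + 1L
      else if (call$label != as.character(truth[[p]]))
        out["err"] <- out["err"] + 1L
    }
    out
  }
  clean <- rowSums(vapply(1:25, run_one, numeric(3), d = 0, e = 0))
  noisy <- rowSums(vapply(1:25, run_one, numeric(3), d = 0.3, e = 0.1))
  # recombination inside the window mostly abstains; the rare double
  # crossover (proband + fetus) is an inherent blind spot
  xo <- rowSums(vapply(1:25, run_one, numeric(3), d = 0, e = 0, xo = 1))
  expect_identical(clean[["err"]], 0)
  expect_identical(clean[["amb"]], 0)
  expect_gte(noisy[["amb"]], clean[["amb"]])
  # unambiguous calls stay overwhelmingly correct even under heavy noise
  expect_lte(noisy[["err"]], 1)
  expect_lte(xo[["err"]], 2)
  expect_gt(xo[["amb"]], 0)
})
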