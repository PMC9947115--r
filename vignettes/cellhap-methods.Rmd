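---
title: "Haplotype-based diagnosis from single fetal cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based diagnosis from single fetal cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellhap)
```

## The problem

Circulating trophoblast cells in maternal blood carry a complete fetal
genome and can be captured non-invasively during early pregnancy. A
single cell, however, must be whole-genome amplified (WGA) before
sequencing, and WGA is noisy: at a heterozygous site one allele often
fails to amplify (allele dropout, ADO), and amplification and
genotyping errors corrupt a further fraction of calls. Observed ADO
rates around 17–20% and genotype discordances around 27–30% against a
matched amniotic-fluid control make direct mutation reading unsafe for
diagnosis.

`cellhap` implements the standard remedy for a family with a previously
diagnosed child (the proband): *relative haplotype phasing*. Rather than
trusting the genotype at the pathogenic position itself, the method
asks which parental haplotype the fetus inherited around that position,
using many flanking SNPs so that no single dropout or error can flip
the answer.

## The model

### Informative SNPs and phasing

Within a window of ±`flank` (default 2 Mb, so ~4 Mb total) around the
pathogenic locus, a biallelic SNP is *informative from the father*
(IFF) when the father is heterozygous and the mother homozygous, and
*informative from the mother* (IFM) in the mirrored case. At such a
site the homozygous parent's contribution to a child is forced, so the
allele the informative parent transmitted to the proband is obtained by
subtracting the homozygous parent's allele from the proband genotype.
Sites where both parents are heterozygous carry no origin information
and are dropped; so are sites that would make the proband
Mendelian-inconsistent (these are counted and reported).

Each carrier parent's haplotypes are labelled against the disease:
haplotype 1 (P1 or M1) is the one carrying that parent's pathogenic
allele, haplotype 2 the wild-type one. The proband anchors the
labelling: if the proband carries the carrier parent's pathogenic
allele, every allele that parent transmitted to the proband is placed
on haplotype 1, otherwise on haplotype 2. One homologous recombination
is assumed per chromosome per meiosis; within the +/- 2 Mb window the
proband's transmission is treated as recombination-free. A proband
crossover inside the window is undetectable with a single proband — the
simulation modules quantify the induced error (see *Limitations*) but
the caller makes no attempt to correct it.

### Key SNPs and voting

The single cell is then read at every informative SNP. An observation
is robust evidence — a *key SNP* — exactly when it cannot be produced
from the competing transmission hypothesis by dropping one allele.
Operationally: the observation must contain the *distinguishing
allele*, i.e. the informative parent's allele that the homozygous
parent does not carry. An observation homozygous for the shared allele
is compatible with either transmission once a dropout is allowed, and a
missing observation says nothing; both are non-key. For a hemizygous
cell (male fetus on the X) every called site is key, because the single
observed allele *is* the maternal transmission.

Each key SNP votes for the haplotype carrying its identified allele.
Votes are tallied separately upstream and downstream of the locus; a
flank decides when it has at least `min_key_per_flank` votes (default
1) and the majority reaches `vote_threshold` (default 0.8). The call is
the common flank decision. Discordant flanks indicate a possible fetal
recombination between the flanks and yield an *ambiguous* call with a
recombination flag — a deliberately conservative clinical posture; no
forced label is ever produced from discordant flanks.

Key-SNP marking is evaluated against the observed cell genotype
(default `mode = "observation"`), since whether a locus "may be
affected by dropout" is only decidable per observation. A stricter
`mode = "het_only"` accepts only heterozygous cell observations: a
homozygous-distinguishing observation still identifies the transmission
but is itself a dropout survivor. The default keeps those observations
because they vote for the same haplotype the full genotype would; the
choice only matters near the vote threshold.

### Verdicts

For an autosomal-recessive locus with both parents carriers, the four
combinations map to: P1/M1 affected, P1/M2 carrier (paternal), P2/M1
carrier (maternal), P2/M2 normal. X-linked loci use the maternal call
alone: M1 means affected for a male fetus and carrier for a female.
Dominant loci map the carrier parent's haplotype 1 to affected. Any
required call that is ambiguous makes the verdict ambiguous.

### QC metrics

With a reference sample (amniotic fluid, villi, or the simulation
truth):

* **ADO ratio** — among reference-heterozygous sites with a cell call,
  the fraction called homozygous in the cell.
* **FP ratio** — among sites called in both samples, the fraction with
  different genotypes. Any difference counts, so dropout-induced
  het-to-hom changes contribute; their share is reported separately so
  the dropout-free discordance can be recomputed. Both denominators are
  reported because "total SNPs" normalisations differ between studies.
* **Coverage** — fraction of sites with at least one read (a site-level
  surrogate for base-level genome coverage), plus interval-level panel
  coverage (`region_overlap`: covered panel bases over total panel
  bases).
* **Haplotypable genes** — genes with at least one key SNP strictly
  upstream and at least one strictly downstream within the flank.

Under the observation model below these metrics have closed forms:
a truly heterozygous site is observed homozygous with probability
$(2d(1-e)+e)/(1+d)$ (per-allele dropout $d$, genotype-error rate $e$),
which reduces to $2d/(1+d)$ when $e = 0$; the overall discordance is
$H \cdot \mathrm{ADO}(d,e) + (1-H)e$ with $H$ the heterozygous fraction
among co-called sites. `recover_wga_rates()` inverts the two identities,
so injected artifact rates are recoverable from the measured metrics —
the basis of the parameter-recovery tests.

## The synthetic-data generator

No sequencing data ship with the package; every analysis is exercised
on simulated families with fully known truth.

* **Sites.** `n_snps` positions uniform over a `region_span` window
  centred on the locus; alternate-allele frequency uniform on
  (0.05, 0.5] per site. Defaults: 6,000 SNPs over 4 Mb, matching the
  SNP yield such windows show at whole-genome depth (panel sequencing
  of the same window yields ~700–800).
* **Pathogenic variants.** One heterozygous variant per carrier parent,
  planted on haplotype 1; compound-heterozygous families get two
  distinct nearby positions (default 500 bp apart).
* **Meiosis.** Per transmitted chromosome, one crossover with
  probability `crossover_prob` at a uniform breakpoint, never more.
  The default 0.05 approximates the chance that the single exchange of
  a ~100–200 Mb chromosome falls inside a 4 Mb window, rounded up to
  keep the recombination path exercised. The proband always inherits
  the pathogenic haplotype(s) — it is the affected child.
* **Bulk samples.** Parents, proband and the reference are gDNA:
  Poisson depth (mean `gdna_depth` = 30), faithful genotypes, reads
  split deterministically between alleles, missing only below the depth
  threshold. gDNA does not suffer WGA allelic imbalance, and a
  deterministic split keeps noise-free contracts exact.
* **The cell.** Per site: depth negative-binomial with mean
  `mean_depth` (default 15, the depth at which coverage and artifact
  rates plateau; dispersion `Inf` = Poisson limit, smaller values mimic
  WGA non-uniformity); each true allele dropped independently with
  probability `ado_rate`; with probability `fp_rate` the surviving
  genotype is replaced by a uniformly chosen different genotype; reads
  split binomially between surviving alleles; genotypes re-called with
  the depth-threshold caller. Sites with both alleles dropped yield no
  reads. Site-level missingness thus *emerges* from dropout plus the
  depth filter rather than being a separate parameter. Default artifact
  rates (`ado_rate` 0.2, `fp_rate` 0.05) are the stress condition used
  throughout the recovery experiments; the resulting *observed* ADO of
  ~36% is deliberately harsher than the ~17–20% seen in real cells.
* **Caller.** Calls require depth strictly greater than
  `min_call_depth` (default 10, i.e. "coverage > 10"); a read-quality
  cutoff is not reproducible without reads, so the caller instead uses
  `min_alt_fraction` (default 0.2): heterozygous when both alleles hold
  at least that fraction of reads. At marginal depths the binomial read
  split alone occasionally miscalls a heterozygote — which is why
  measured ADO/FPR improve with depth up to ~15x even at fixed artifact
  rates, reproducing the gradient behaviour qualitatively.
* **Depth gradients.** `downsample_depth()` thins reads binomially;
  `depth_gradient_analysis()` couples the thinnings (each gradient
  thinned from the next higher), so per-site read counts are monotone
  within a sweep while each gradient keeps its correct marginal. At 1x
  mean depth no site passes the `>10` filter, so ADO/FPR are reported
  as missing there.
* **STR profiles.** 16 loci (15 autosomal + amelogenin): parental
  alleles uniform integer repeats, the cell inherits one allele per
  parent, and each cell locus is hidden with probability
  `1 - detection_rate` (default 0.75, the detection regime reported for
  real cells). Amelogenin is counted for detection but excluded from
  paternal-specific scoring; "multiple paternal alleles" defaults to
  at least 2. Cell alleles found in neither parent are flagged but not
  counted.

What the generator does **not** emulate: read-level artifacts (GC bias,
chimeric WGA fragments), base-quality structure, linkage disequilibrium
between SNPs, population allele-frequency spectra, multi-allelic sites,
and fetoplacental mosaicism. Passing tests therefore demonstrate the
correctness of the inference logic under the stated noise model, not
performance on any particular sequencing platform.

## Worked example

```{r example}
cfg <- run_config(sim = sim_config(seed = 1))
report <- run_pipeline(cfg)
report
```

The planted truth is available for comparison:

```{r truth}
report$truth
```

```{r plot, fig.width = 7, fig.height = 3}
plot_haplotype_track(report$informative, report$family$locus)
```

## Numerical choices and degenerate inputs

* Thresholds are strict (`depth > 10`) to match the conventional
  filter; a depth of exactly 10 is missing.
* A flank with no key SNPs, or a majority below the vote threshold,
  abstains; the verdict then reports *why* (diagnostic message).
* Zero-denominator metrics (e.g. ADO for a male X cell, whose reference
  is never heterozygous) are `NA` with `n = 0`, never 0.
* Ties: a diploid site with equal read counts is heterozygous whenever
  `min_alt_fraction` ≤ 0.5; hemizygous ties take the reference allele.
* The vote threshold 0.8 with a minimum of one key SNP per flank is a
  package default — reports only ever show supporting counts per flank,
  so the rule is configurable and logged in every call object.
* Seeds: every stochastic stage derives its stream from the
  configuration seed (family, observation, STR, panel, thinning use
  fixed offsets), so a run is reproducible end to end.

## Problem sizes used in the validation suite

The shipped tests run entirely on simulated data at desk scale:
closed-form and parameter-recovery checks use 10^5 sites (Monte-Carlo
standard errors ~0.2 percentage points); haplotype recovery uses 200
cells at 6,000 SNPs with at least five key SNPs required per flank;
the exhaustive-oracle comparison enumerates 1,000 random instances of
up to 12 informative SNPs; gradient behaviour uses 20 replicate sweeps
of 20,000 sites over the eight standard gradients (1x–35x). Headline
per-cell metrics published for real cells derive from deposited
sequencing reads and are not reproduction targets of this package.

## Limitations

* A proband is required; families without a diagnosed child cannot be
  phased this way (population-reference or multi-cell phasing is out of
  scope).
* Recombination between the flanks yields an ambiguous call by design;
  recombination *within* a flank shifts its vote fraction and usually
  trips the threshold instead. The one blind spot is a double
  crossover — proband and fetus both recombining near the locus — which
  can produce a concordant wrong call; under the default crossover
  probability this affects well under 1% of calls in simulation, and it
  is inherent to single-proband phasing rather than to this
  implementation.
* X-linked support covers a carrier mother; an affected hemizygous
  father is not modelled.
* All coordinates are 1-based inclusive in memory and in VCF; BED
  output is 0-based half-open.
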