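Package: cellhap
Title: Trio-Anchored Haplotype Analysis for Cell-Based Noninvasive
    Prenatal Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a haplotype-based analysis of single circulating
    trophoblast cells for noninvasive prenatal diagnosis of monogenic
    disease. From multi-sample genotypes of the father, mother, proband
    and a candidate fetal cell, the package classifies informative SNPs,
    phases parental haplotypes against a pathogenic locus, calls the
    inherited fetal haplotypes by flank-wise key-SNP voting and maps
    them to a diagnostic verdict. Companion modules confirm the fetal
    origin of a cell from STR profiles, compute sequencing quality
    metrics (allele dropout, genotype discordance, coverage, number of
    genes amenable to haplotyping) across read-depth gradients, and
    simulate families, whole-genome-amplified single-cell genotypes and
    STR profiles with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
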