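# Independent brute-force oracles. These deliberately share no code with
# the implementation: per-base membership counting, site-by-site loops,
# and exhaustive hypothesis enumeration.

# Per-base overlap fraction for BED-style data.frames (0-based half-open).
bf_region_overlap <- function(covered, panel) {
  base_set <- function(df) {
    unlist(lapply(seq_len(nrow(df)), function(i) {
      if (df$end[i] <= df$start[i]) return(character(0))
      paste(df$chrom[i], seq(df$start[i] + 1, df$end[i]))
    }))
  }
  pb <- unique(base_set(panel))
  cb <- unique(base_set(covered))
  sum(pb %in% cb) / length(pb)
}

# Site-by-site recount of the allele-dropout ratio.
bf_ado <- function(cell_gt, ref_gt) {
  num <- 0L; den <- 0L
  for (i in seq_along(cell_gt)) {
    if (is.na(ref_gt[i]) || ref_gt[i] != "0/1") next
    if (is.na(cell_gt[i])) next
    den <- den + 1L
    if (cell_gt[i] %in% c("0/0", "1/1", "0", "1")) num <- num + 1L
  }
  if (den == 0) NA_real_ else num / den
}

# Site-by-site recount of the discordance (false-positive) ratio.
bf_fpr <- function(cell_gt, ref_gt) {
  num <- 0L; den <- 0L
  for (i in seq_along(cell_gt)) {
    if (is.na(cell_gt[i]) || is.na(ref_gt[i])) next
    den <- den + 1L
    if (cell_gt[i] != ref_gt[i]) num <- num + 1L
  }
  if (den == 0) NA_real_ else num / den
}

# Per-gene scan for the haplotypable-gene rule. Genes are given 1-based
# inclusive; the flanks are open intervals excluding the gene body.
bf_haplotypable <- function(genes, snps, flank) {
  count <- 0L
  for (i in seq_len(nrow(genes))) {
    on_chrom <- snps$pos[snps$chrom == genes$chrom[i]]
    up <- any(on_chrom > genes$start[i] - flank & on_chrom < genes$start[i])
    dn <- any(on_chrom > genes$end[i] & on_chrom < genes$end[i] + flank)
    if (up && dn) count <- count + 1L
  }
  count
}

# Exhaustive haplotype oracle: enumerate both transmission hypotheses x
# all single-allele dropout patterns; a hypothesis survives when every
# observed cell genotype is reachable from it by dropping at most one
# allele at that site. Decisive = exactly one surviving hypothesis.
oracle_haplotype <- function(phased, cell_gt) {
  reachable <- function(trans, shared, hemi) {
    if (hemi) return(as.character(trans))
    full <- paste(min(trans, shared), max(trans, shared), sep = "/")
    unique(c(full,
             paste(trans, trans, sep = "/"),
             paste(shared, shared, sep = "/")))
  }
  consistent <- function(H) {
    for (i in seq_len(nrow(phased))) {
      obs <- cell_gt[i]
      if (is.na(obs)) next
      hemi <- obs %in% c("0", "1")
      trans <- if (H == 1L) phased$hap1_allele[i] else 1L - phased$hap1_allele[i]
      if (!(obs %in% reachable(trans, phased$shared_allele[i], hemi)))
        return(FALSE)
    }
    TRUE
  }
  ok <- c(consistent(1L), consistent(2L))
  if (sum(ok) == 1) list(decisive = TRUE, label = which(ok))
  else list(decisive = FALSE, label = NA_integer_)
}

# Mendelian check from genotype strings alone: child alleles must be
# splittable into one allele from each parent's genotype.
mendel_ok <- function(child, father, mother) {
  split_gt <- function(g) strsplit(g, "/", fixed = TRUE)[[1]]
  ca <- split_gt(child)
  fa <- split_gt(father); ma <- split_gt(mother)
  if (length(ca) == 1) return(ca %in% ma)  # hemizygous: maternal X
  any(vapply(seq_along(ca), function(k)
    ca[k] %in% fa && ca[-k] %in% ma, logical(1)))
}
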