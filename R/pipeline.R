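# End-to-end orchestration: simulate -> confirm -> QC -> haplotype ->
# verdict, as a pure function of (config, seed).

#' Pipeline run configuration
#'
#' @param sim a [sim_config()] describing the family and the cell.
#' @param flank phasing window half-width in bp.
#' @param vote_threshold,min_key_per_flank voting thresholds, see
#'   [call_fetal_haplotype()].
#' @param key_mode key-SNP marking mode, see [mark_key_snps()].
#' @param str_n_loci,str_detection_rate,str_threshold STR confirmation
#'   parameters, see [simulate_str_profiles()] and
#'   [classify_fetal_origin()].
#' @param n_panel_genes size of the simulated gene panel.
#' @param depth_gradients optional numeric vector of target depths; when
#'   set, a [depth_gradient_analysis()] is included in the report.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), flank = 2e6,
                       vote_threshold = 0.8, min_key_per_flank = 1L,
                       key_mode = "observation",
                       str_n_loci = 16L, str_detection_rate = 0.75,
                       str_threshold = 2L,
                       n_panel_genes = 67L,
                       depth_gradients = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, flank = flank,
                 vote_threshold = vote_threshold,
                 min_key_per_flank = as.integer(min_key_per_flank),
                 key_mode = key_mode,
                 str_n_loci = as.integer(str_n_loci),
                 str_detection_rate = str_detection_rate,
                 str_threshold = as.integer(str_threshold),
                 n_panel_genes = as.integer(n_panel_genes),
                 depth_gradients = depth_gradients),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full cbNIPT analysis pipeline on a simulated family
#'
#' Executes, in order: family simulation, single-cell observation, STR
#' fetal-origin confirmation, QC metrics against the reference sample,
#' informative-SNP classification, phasing, key-SNP marking, per-parent
#' haplotype calls and the diagnostic verdict. The run is a pure
#' function of its configuration: the same `config` reproduces the
#' report bit for bit. When `out_dir` is given, stage outputs (VCF, STR
#' TSV, informative-SNP TSV, JSON report) are written there.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return an object of class `run_report` with elements `verdict`,
#'   `calls`, `qc`, `str`, `informative`, `truth` (planted fetal
#'   haplotypes and the verdict they imply) and `gradient` (when
#'   configured).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  truth <- stage("simulate", simulate_family(config$sim))
  table <- stage("observe", observe_single_cell(truth, config$sim))
  locus <- truth$locus

  strp <- stage("str_confirm", {
    profiles <- simulate_str_profiles(truth, n_loci = config$str_n_loci,
                                      detection_rate = config$str_detection_rate)
    psa <- paternal_specific_alleles(profiles$cell, profiles$father,
                                     profiles$mother)
    list(profiles = profiles,
         detection_rate_pct = str_detection_rate(profiles$cell),
         paternal_specific = psa,
         confirmed_fetal = classify_fetal_origin(psa$count,
                                                 config$str_threshold))
  })

  hap <- stage("haplotype", {
    inf <- classify_informative_snps(table, locus, flank = config$flank)
    ph <- phase_to_pathogenic(inf, table, locus)
    keyed <- mark_key_snps(ph, table, mode = config$key_mode)
    parents <- intersect(c("father", "mother"), locus$carrier_parents)
    if (locus$inheritance_mode == "x_linked") parents <- "mother"
    calls <- lapply(parents, function(p)
      call_fetal_haplotype(keyed, parent = p,
                           vote_threshold = config$vote_threshold,
                           min_key_per_flank = config$min_key_per_flank))
    names(calls) <- ifelse(parents == "father", "paternal", "maternal")
    list(informative = keyed, calls = calls)
  })

  verdict <- stage("verdict",
                   derive_verdict(paternal = hap$calls$paternal,
                                  maternal = hap$calls$maternal,
                                  locus = locus,
                                  fetal_sex = config$sim$fetal_sex))

  qc <- stage("qc", {
    panel <- simulate_gene_panel(truth, n_genes = config$n_panel_genes)
    keys <- hap$informative[hap$informative$key, c("chrom", "pos")]
    sr <- site_ranges(table)
    dp <- get_dp(table, "CELL")
    in_panel <- GenomicRanges::countOverlaps(sr, panel,
                                             ignore.strand = TRUE) > 0
    hits <- GenomicRanges::findOverlaps(sr, panel, ignore.strand = TRUE)
    covered_genes <- length(unique(
      S4Vectors::subjectHits(hits)[dp[S4Vectors::queryHits(hits)] >= 1]))
    list(ado_ratio = ado_ratio(table, table),
         fp_ratio = false_positive_ratio(table, table),
         genome_coverage = genome_coverage(table, "CELL"),
         panel_coverage = mean(dp[in_panel] >= 1),
         panel_genes_total = length(panel),
         panel_genes_covered = covered_genes,
         panel_genes_haplotypable =
           as.integer(haplotypable_gene_count(panel, keys,
                                              flank = config$flank)),
         panel = panel)
  })

  gradient <- NULL
  if (!is.null(config$depth_gradients))
    gradient <- stage("depth_sweep",
                      depth_gradient_analysis(
                        table, depths = config$depth_gradients,
                        source_depth = config$sim$mean_depth,
                        panels = list(panel = qc$panel),
                        seed = config$sim$seed + 4000L,
                        min_call_depth = config$sim$min_call_depth,
                        min_alt_fraction = config$sim$min_alt_fraction))

  truth_haps <- true_fetal_haplotypes(truth)
  truth_verdict <- verdict_from_labels(
    pat = if ("paternal" %in% names(truth_haps))
      as.character(truth_haps[["paternal"]]) else NULL,
    mat = if ("maternal" %in% names(truth_haps))
      as.character(truth_haps[["maternal"]]) else NULL,
    locus = locus, fetal_sex = config$sim$fetal_sex)

  report <- structure(
    list(config = config, verdict = verdict, calls = hap$calls,
         qc = qc[setdiff(names(qc), "panel")], str = strp,
         informative = hap$informative,
         n_informative = nrow(hap$informative),
         n_key = sum(hap$informative$key),
         truth = list(fetal_haplotypes = truth_haps,
                      verdict = truth_verdict),
         table = table, family = truth),
    class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_family_vcf(table, file.path(out_dir, "family.vcf"))
    write_str_profiles(strp$profiles, file.path(out_dir, "str_profiles.tsv"))
    write.table(hap$informative, file.path(out_dir, "informative_snps.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_panel_bed(qc$panel, file.path(out_dir, "panel.bed"))
    write_report_json(report, file.path(out_dir, "report.json"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

# Serialisable core of a report (drops the heavy table/family objects).
report_core <- function(report) {
  calls <- lapply(report$calls, function(cl)
    list(parent = cl$parent, label = cl$label,
         up_votes = as.list(cl$up_votes), down_votes = as.list(cl$down_votes),
         recombination_flag = cl$recombination_flag,
         message = cl$message))
  list(verdict = report$verdict$value,
       inheritance_mode = report$verdict$inheritance_mode,
       fetal_sex = report$verdict$fetal_sex,
       calls = calls,
       qc = list(ado_ratio = as.numeric(report$qc$ado_ratio),
                 ado_n = attr(report$qc$ado_ratio, "n"),
                 fp_ratio = as.numeric(report$qc$fp_ratio),
                 fp_n = attr(report$qc$fp_ratio, "n"),
                 genome_coverage = report$qc$genome_coverage,
                 panel_coverage = report$qc$panel_coverage,
                 panel_genes_total = report$qc$panel_genes_total,
                 panel_genes_covered = report$qc$panel_genes_covered,
                 panel_genes_haplotypable = report$qc$panel_genes_haplotypable),
       str = list(detection_rate_pct = report$str$detection_rate_pct,
                  paternal_specific_count = report$str$paternal_specific$count,
                  confirmed_fetal = report$str$confirmed_fetal),
       n_informative = report$n_informative,
       n_key = report$n_key,
       truth = list(
         fetal_haplotypes = as.list(report$truth$fetal_haplotypes),
         verdict = report$truth$verdict),
       seed = report$config$sim$seed)
}

#' Write / read the machine-readable run report
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param path JSON file path.
#' @return `read_report_json()`: the report core as a list.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_core(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Render a human-readable run summary
#'
#' @param report a `run_report` from [run_pipeline()] or a list read
#'   back by [read_report_json()].
#' @return character vector of summary lines.
#' @export
render_report <- function(report) {
  core <- if (inherits(report, "run_report")) report_core(report) else report
  fmt_call <- function(cl) {
    line <- sprintf("  %s: haplotype %s (upstream %d/%d, downstream %d/%d key votes hap1/hap2)",
                    cl$parent, cl$label,
                    cl$up_votes$hap1, cl$up_votes$hap2,
                    cl$down_votes$hap1, cl$down_votes$hap2)
    extra <- character(0)
    if (isTRUE(cl$recombination_flag))
      extra <- "    recombination flag: flank discordance"
    if (!is.null(cl$message) && length(cl$message) > 0 && nzchar(cl$message[[1]]))
      extra <- c(extra, paste0("    ", cl$message[[1]]))
    c(line, extra)
  }
  c(sprintf("cbNIPT run (seed %d)", core$seed),
    sprintf("verdict: %s  [%s, fetal sex %s]", core$verdict,
            core$inheritance_mode, core$fetal_sex),
    unlist(lapply(core$calls, fmt_call)),
    sprintf("informative SNPs: %d (%d key)", core$n_informative, core$n_key),
    sprintf("QC: ADO %.1f%% (n=%d), FPR %.1f%% (n=%d), genome coverage %.1f%%",
            100 * core$qc$ado_ratio, core$qc$ado_n,
            100 * core$qc$fp_ratio, core$qc$fp_n,
            100 * core$qc$genome_coverage),
    sprintf("panel: coverage %.1f%%, %d/%d genes covered, %d haplotypable",
            100 * core$qc$panel_coverage, core$qc$panel_genes_covered,
            core$qc$panel_genes_total, core$qc$panel_genes_haplotypable),
    sprintf("STR: detection %.2f%%, %d paternal-specific allele(s), fetal origin %s",
            core$str$detection_rate_pct, core$str$paternal_specific_count,
            if (isTRUE(core$str$confirmed_fetal)) "confirmed" else "not confirmed"))
}

#' Haplotype-support track of informative SNPs
#'
#' Plots each phased informative SNP along the window, coloured by the
#' haplotype it votes for, with key SNPs emphasised and the pathogenic
#' locus marked — the per-SNP inheritance track accompanying a call.
#'
#' @param phased result of [mark_key_snps()].
#' @param locus the [disease_locus()].
#' @return a ggplot object.
#' @export
plot_haplotype_track <- function(phased, locus) {
  stopifnot(inherits(phased, "informative_snps"))
  df <- as.data.frame(phased)
  df$support <- ifelse(is.na(df$vote_hap), "non-key",
                       paste0("haplotype ", df$vote_hap))
  df$parent <- factor(df$parent, levels = c("father", "mother"),
                      labels = c("paternal (P1/P2)", "maternal (M1/M2)"))
  df$pos_mb <- df$pos / 1e6
  ggplot2::ggplot(df, ggplot2::aes(x = pos_mb, y = parent,
                                   colour = support, shape = key)) +
    ggplot2::geom_jitter(width = 0, height = 0.15, size = 1.5, alpha = 0.8) +
    ggplot2::geom_vline(xintercept = locus$position / 1e6, linetype = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "key SNP") +
    ggplot2::labs(x = sprintf("%s position (Mb)", locus$chrom), y = NULL,
                  colour = "supports",
                  title = sprintf("Informative SNPs around %s", locus$gene)) +
    ggplot2::theme_minimal()
}
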