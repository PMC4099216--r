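#' Run the full ASE pipeline
#'
#' Stages, in order: intensity normalization (per template), QC (call-rate,
#' HWE, cDNA contamination), ASE windows, cis-rSNP association, enhancer
#' enrichment, co-expression, GWAS-catalog overlap. Any of the last three
#' stages can be skipped by name. Rerunning with identical inputs and
#' configuration reproduces identical outputs.
#'
#' @param bundle An `ase_bundle` ([simulate_bundle()] or [read_bundle()]).
#' @param config Configuration list (see [default_config()]).
#' @param output_dir If non-NULL, all result tables are written there.
#' @param skip Character vector of stage names to skip, from
#'   `c("enrichment", "coexpression", "gwas")`.
#' @param quiet Suppress per-stage log lines on stderr.
#' @return A list with `qc`, `windows`, `associations`, `enrichment`,
#'   `coexpression`, `gwas_overlap`, `trait_enrichment` and `manifest`
#'   (the filter-funnel record counts).
#' @export
run_pipeline <- function(bundle, config = default_config(), output_dir = NULL,
                         skip = character(0), quiet = FALSE) {
  stopifnot(inherits(bundle, "ase_bundle"))
  bad_skip <- setdiff(skip, c("enrichment", "coexpression", "gwas"))
  if (length(bad_skip) > 0L) {
    stop(sprintf("unknown stage in skip: %s", paste(bad_skip, collapse = ", ")))
  }
  log_line <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }

  # normalize ---------------------------------------------------------------
  het_mask <- !is.na(bundle$genotypes) & bundle$genotypes == "AB"
  gdna_models <- fit_template_models(bundle$gdna_x, bundle$gdna_y, het_mask,
                                     n_bins = config$norm.n_bins)
  cdna_models <- fit_template_models(bundle$cdna_x, bundle$cdna_y, het_mask,
                                     n_bins = config$norm.n_bins)
  gdna_frac <- adjust_fraction_matrix(bundle$gdna_x, bundle$gdna_y, gdna_models)
  cdna_frac <- adjust_fraction_matrix(bundle$cdna_x, bundle$cdna_y, cdna_models)
  log_line("normalize", "fitted %d-bin quadratic models for 2 templates x 2 channels",
           config$norm.n_bins)

  # qc -----------------------------------------------------------------------
  qc <- run_qc(bundle$genotypes, bundle$cdna_calls, config)
  log_line("qc", "kept %d/%d SNPs, %d/%d samples (removed: callrate %d SNPs, hwe %d SNPs, callrate %d samples, contamination %d samples)",
           length(qc$snps), ncol(bundle$genotypes),
           length(qc$samples), nrow(bundle$genotypes),
           qc$report$snps_removed_callrate, qc$report$snps_removed_hwe,
           qc$report$samples_removed_callrate,
           qc$report$samples_removed_contamination)
  ss <- qc$samples
  kk <- qc$snps

  # ase ----------------------------------------------------------------------
  ase <- ase_snp_matrix(gdna_frac[ss, kk, drop = FALSE],
                        cdna_frac[ss, kk, drop = FALSE],
                        bundle$genotypes[ss, kk, drop = FALSE],
                        bundle$phased$hap1[ss, kk, drop = FALSE])
  windows <- compute_ase_windows(bundle$regions, bundle$panel, ase,
                                 bundle$cdna_x[ss, , drop = FALSE],
                                 bundle$cdna_y[ss, , drop = FALSE],
                                 config)
  log_line("ase", "%d/%d regions informative, %d expressed, %d pass both",
           sum(windows$summary$informative), nrow(windows$summary),
           sum(windows$summary$expressed), sum(windows$summary$passed))

  # associate ------------------------------------------------------------------
  phased_qc <- list(hap1 = bundle$phased$hap1[ss, , drop = FALSE],
                    hap2 = bundle$phased$hap2[ss, , drop = FALSE])
  associations <- test_associations(bundle$regions, windows, bundle$panel,
                                    phased_qc, config)
  log_line("associate", "%d tests, %d significant",
           nrow(associations), sum(associations$significant))

  # enrich ---------------------------------------------------------------------
  enrichment <- NULL
  if (!"enrichment" %in% skip && length(bundle$peaks) > 0L) {
    enrichment <- run_enrichment(associations, bundle$regions, bundle$panel,
                                 bundle$peaks, config)
    log_line("enrich", "%d consensus peak sets, %d enrichment rows",
             length(enrichment$peaks), nrow(enrichment$table))
  }

  # coexpress ------------------------------------------------------------------
  coexpression <- NULL
  if (!"coexpression" %in% skip) {
    coexpression <- run_coexpression(associations, bundle$regions, bundle$panel,
                                     phased_qc,
                                     bundle$cdna_x[ss, , drop = FALSE],
                                     bundle$cdna_y[ss, , drop = FALSE],
                                     config)
    log_line("coexpress", "%d pairs tested, %d pass FDR %.0f%%",
             nrow(coexpression), sum(coexpression$fdr_pass),
             100 * config$coexpr.fdr_q)
  }

  # gwas -----------------------------------------------------------------------
  gwas_overlap <- NULL
  trait_enr <- NULL
  if (!"gwas" %in% skip && !is.null(bundle$catalog)) {
    haps <- matrix(0L, 2L * length(ss), ncol(bundle$phased$hap1),
                   dimnames = list(NULL, colnames(bundle$phased$hap1)))
    haps[2L * seq_along(ss) - 1L, ] <- bundle$phased$hap1[ss, , drop = FALSE]
    haps[2L * seq_along(ss), ] <- bundle$phased$hap2[ss, , drop = FALSE]
    lnc_ids <- mcols(bundle$regions)$region_id[
      mcols(bundle$regions)$region_class != "protein_coding"]
    lnc_assoc <- associations[associations$region_id %in% lnc_ids, , drop = FALSE]
    gwas_overlap <- overlap_catalog(lnc_assoc, bundle$catalog, haps,
                                    r2_thresh = config$gwas.r2_thresh)
    if (!is.null(enrichment)) {
      gwas_overlap <- annotate_enhancer_context(gwas_overlap, bundle$panel,
                                                enrichment$peaks,
                                                config$enrich.flank_bp)
    }
    trait_enr <- trait_enrichment(gwas_overlap, bundle$catalog)
    log_line("gwas", "%d overlap records; immune over-representation p = %s",
             nrow(gwas_overlap), format(trait_enr$fisher_p, digits = 3))
  }

  lnc_summary <- windows$summary[windows$summary$region_class != "protein_coding", ]
  sig_regions <- unique(associations$region_id[associations$significant])
  manifest <- data.frame(
    regions_total = nrow(lnc_summary),
    regions_informative = sum(lnc_summary$informative),
    regions_expressed = sum(lnc_summary$informative & lnc_summary$expressed),
    regions_significant = length(intersect(sig_regions, lnc_summary$region_id)),
    snps_tested = length(unique(associations$snp_id)),
    snps_significant = length(unique(associations$snp_id[associations$significant])),
    samples_retained = length(ss),
    snps_retained = length(kk)
  )

  result <- list(qc = qc, windows = windows, associations = associations,
                 enrichment = enrichment, coexpression = coexpression,
                 gwas_overlap = gwas_overlap, trait_enrichment = trait_enr,
                 manifest = manifest,
                 models = list(gdna = gdna_models, cdna = cdna_models))
  if (!is.null(output_dir)) write_results(result, output_dir)
  result
}

#' Write all pipeline result tables
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  fwrite(as.data.table(result$qc$report), fp("qc_report.tsv"), sep = "\t")
  write_ase_windows(result$windows, fp("ase_windows.tsv"))
  fwrite(as.data.table(result$associations), fp("associations.tsv"),
         sep = "\t", na = "NA", quote = FALSE)
  if (!is.null(result$enrichment)) {
    fwrite(as.data.table(result$enrichment$table), fp("enrichment.tsv"),
           sep = "\t", na = "NA", quote = FALSE)
  }
  if (!is.null(result$coexpression)) {
    fwrite(as.data.table(result$coexpression), fp("coexpression.tsv"),
           sep = "\t", na = "NA", quote = FALSE)
  }
  if (!is.null(result$gwas_overlap)) {
    fwrite(as.data.table(result$gwas_overlap), fp("gwas_overlap.tsv"),
           sep = "\t", na = "NA", quote = FALSE)
  }
  fwrite(as.data.table(result$manifest), fp("run_manifest.tsv"), sep = "\t")
  invisible(dir)
}
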