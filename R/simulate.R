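#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults mirror the study
#' conditions the pipeline is designed for: 188 samples, heterozygote cDNA
#' fraction 0.6 under a cis effect (window ASE around 0.1, twice the 0.05
#' slope threshold), per-SNP allele-fraction noise sd 0.05, mean expressed
#' total intensity 3300 fluorescence units, and a smooth intensity-dependent
#' dye bias on the x channel of the class the normalization models.
#'
#' @param n_samples Number of samples.
#' @param n_regions Number of lncRNA regions (each gets a companion
#'   protein-coding region).
#' @param snps_per_region SNPs inside each region.
#' @param n_flank_snps Candidate SNPs placed in the 250 kb flanks.
#' @param maf_range Uniform range for minor-allele frequencies.
#' @param ld_block_rho Gaussian-copula correlation of adjacent SNPs within
#'   a region block.
#' @param cis_effect_fraction Fraction of lncRNA regions given a true
#'   cis-rSNP.
#' @param het_cdna_fraction_under_effect cDNA fraction of the overexpressed
#'   haplotype in heterozygous carriers of the effect allele.
#' @param intensity_log_mean,intensity_log_sd Natural-log mean/sd of the
#'   per-region expressed cDNA intensity (region-to-region spread).
#' @param within_region_log_sd Natural-log sd of per-SNP/sample total
#'   intensity around the region level.
#' @param gdna_log_mean,gdna_log_sd Lognormal parameters of gDNA totals.
#' @param flank_log_mean Log mean cDNA intensity of non-transcribed flank
#'   SNPs (they must fail the expression threshold).
#' @param dye_bias_coeffs (b0, b1, b2): the x channel is multiplied by
#'   `b0 + b1*log10(total) + b2*log10(total)^2`.
#' @param noise_sd Gaussian sd added to every observed allele fraction.
#' @param call_missing_rate gDNA no-call probability for a normal SNP.
#' @param frac_lowcall_snps Fraction of SNPs with a degraded (95%) call
#'   rate, removed by the 99% call-rate filter.
#' @param frac_hwe_bad_snps Fraction of SNPs made all-heterozygous (gross
#'   HWE violation), removed by the HWE filter.
#' @param n_contaminated Samples given a gDNA-like cDNA call rate.
#' @param cdna_call_range Uniform range of per-sample cDNA call rates for
#'   clean samples.
#' @param coreg_fraction,lnc_only_fraction,unknown_fraction Among effect
#'   regions: gene co-regulated by the same cis-rSNP / co-expressed without
#'   gene ASE / gene placed beyond the 250 kb window (not evaluable).
#' @param coexpr_log_slope Log-intensity shift of the companion gene's
#'   expression per allele-B dosage unit, for co-expressed modes.
#' @param peak_width,n_bg_peaks_per_mark,peak_enrichment_odds,
#'   peak_replicate_prob,peak_jitter_sd Peak placement: width, background
#'   count per mark, odds of a peak covering a true cis-rSNP relative to
#'   the background coverage rate, per-replicate emission probability, and
#'   boundary jitter sd (bp).
#' @param catalog_fraction Fraction of true cis-rSNPs entered into the
#'   GWAS catalog.
#' @param n_catalog_decoys Catalog entries drawn from non-effect panel SNPs.
#' @param immune_prob_member,immune_prob_decoy Probability that a catalog
#'   trait is immune-related, for cis-rSNP members and decoys.
#' @param seed Mandatory RNG seed; identical config and seed reproduce
#'   byte-identical bundles.
#' @return A named list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 188L,
                              n_regions = 300L,
                              snps_per_region = 5L,
                              n_flank_snps = 10L,
                              maf_range = c(0.1, 0.5),
                              ld_block_rho = 0.3,
                              cis_effect_fraction = 0.5,
                              het_cdna_fraction_under_effect = 0.6,
                              intensity_log_mean = log(3300),
                              intensity_log_sd = 0.8,
                              within_region_log_sd = 0.4,
                              gdna_log_mean = log(5000),
                              gdna_log_sd = 0.4,
                              flank_log_mean = log(590),
                              dye_bias_coeffs = c(1, 0.075, 0),
                              noise_sd = 0.05,
                              call_missing_rate = 0.002,
                              frac_lowcall_snps = 0.02,
                              frac_hwe_bad_snps = 0.005,
                              n_contaminated = 1L,
                              cdna_call_range = c(0.15, 0.35),
                              coreg_fraction = 0.3,
                              lnc_only_fraction = 0.3,
                              unknown_fraction = 0.1,
                              coexpr_log_slope = 0.3,
                              peak_width = 1000L,
                              n_bg_peaks_per_mark = 1000L,
                              peak_enrichment_odds = 3,
                              peak_replicate_prob = 0.8,
                              peak_jitter_sd = 50,
                              catalog_fraction = 0.3,
                              n_catalog_decoys = 200L,
                              immune_prob_member = 0.6,
                              immune_prob_decoy = 0.2,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_samples >= 2L, cfg$n_regions >= 1L,
            cfg$snps_per_region >= 1L,
            all(cfg$maf_range > 0), all(cfg$maf_range <= 0.5),
            cfg$ld_block_rho >= 0, cfg$ld_block_rho <= 1,
            cfg$cis_effect_fraction >= 0, cfg$cis_effect_fraction <= 1,
            cfg$het_cdna_fraction_under_effect >= 0,
            cfg$het_cdna_fraction_under_effect <= 1,
            cfg$coreg_fraction + cfg$lnc_only_fraction + cfg$unknown_fraction <= 1,
            is.numeric(cfg$seed), length(cfg$seed) == 1L)
  class(cfg) <- "simulation_config"
  cfg
}

# Genome layout used by the generator: regions spaced so that 250 kb
# candidate windows of neighbouring lncRNAs never overlap.
REGION_SPACING <- 1200000L
REGION_WIDTH <- 20000L
N_SIM_CHROMS <- 4L

#' Simulate phased haplotypes for all panel SNPs
#'
#' Per region block, allele frequencies are drawn from `maf_range` and
#' 2 * n_samples haplotypes are generated with a Gaussian AR(1) copula of
#' correlation `ld_block_rho` between adjacent SNPs, so HWE holds by
#' construction once haplotypes are paired into genotypes.
#'
#' @param freqs Allele-B frequency per SNP of the block.
#' @param n_haps Number of haplotypes.
#' @param rho Copula correlation of adjacent SNPs.
#' @return `n_haps`-by-SNP 0/1 matrix.
#' @export
simulate_haplotypes <- function(freqs, n_haps, rho) {
  m <- length(freqs)
  z <- matrix(rnorm(n_haps * m), n_haps, m)
  if (rho > 0 && m > 1L) {
    for (j in 2:m) {
      z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
    }
  }
  h <- matrix(0L, n_haps, m)
  for (j in seq_len(m)) {
    h[, j] <- as.integer(z[, j] < qnorm(freqs[j]))
  }
  h
}

#' Generate a complete synthetic input bundle
#'
#' Produces every input the pipeline consumes -- SNP panel, regions
#' (lncRNA plus companion protein-coding), phased haplotypes, gDNA/cDNA
#' genotype calls, two-channel gDNA and cDNA intensities with injected dye
#' bias, replicate ChIP-seq peak sets enriched near true cis-rSNPs, and a
#' GWAS-catalog-like table -- together with the ground-truth table needed
#' to score every pipeline stage.
#'
#' @param config A [simulation_config()].
#' @return A list of class `ase_bundle` with elements `panel`, `regions`,
#'   `phased`, `genotypes`, `cdna_calls`, `gdna_x`, `gdna_y`, `cdna_x`,
#'   `cdna_y`, `peaks` (list of 4 replicate `GRanges`), `catalog`, `truth`
#'   and `config`.
#' @export
simulate_bundle <- function(config = simulation_config()) {
  set.seed(config$seed)
  ns <- config$n_samples
  nr <- config$n_regions
  spr <- config$snps_per_region
  nfl <- config$n_flank_snps
  sample_ids <- sprintf("S%03d", seq_len(ns))

  # --- region layout -------------------------------------------------------
  chrom_of <- sprintf("chr%d", ((seq_len(nr) - 1L) %% N_SIM_CHROMS) + 1L)
  slot_of <- ((seq_len(nr) - 1L) %/% N_SIM_CHROMS)
  lnc_start <- 1000000L + slot_of * REGION_SPACING
  lnc_end <- lnc_start + REGION_WIDTH

  gene_mode <- rep("none", nr)
  n_eff <- round(config$cis_effect_fraction * nr)
  eff_idx <- sort(sample.int(nr, n_eff))
  if (n_eff > 0L) {
    u <- runif(n_eff)
    gene_mode[eff_idx] <- ifelse(
      u < config$coreg_fraction, "co_regulated",
      ifelse(u < config$coreg_fraction + config$lnc_only_fraction, "lnc_only",
             ifelse(u < config$coreg_fraction + config$lnc_only_fraction +
                      config$unknown_fraction, "unknown", "none")))
  }
  gene_offset <- ifelse(gene_mode == "unknown", 300000L, 50000L)
  gene_start <- lnc_end + gene_offset
  gene_end <- gene_start + REGION_WIDTH

  lnc_ids <- sprintf("lnc%03d", seq_len(nr))
  gene_ids <- sprintf("gene%03d", seq_len(nr))
  regions <- GRanges(
    rep(chrom_of, 2L),
    IRanges(c(lnc_start, gene_start), c(lnc_end, gene_end))
  )
  mcols(regions)$region_id <- c(lnc_ids, gene_ids)
  mcols(regions)$region_class <- rep(c("intergenic", "protein_coding"),
                                     each = nr)

  # --- SNP panel: per lncRNA block, SNPs inside the lncRNA, in its flanks,
  # and inside the companion gene; one LD block per lncRNA ---------------
  panel_rows <- vector("list", nr)
  hap_blocks <- vector("list", nr)
  region_snps <- vector("list", nr)
  gene_snps <- vector("list", nr)
  flank_snps <- vector("list", nr)
  for (r in seq_len(nr)) {
    inside <- as.integer(round(seq(lnc_start[r] + 1000L, lnc_end[r] - 1000L,
                                   length.out = spr)))
    n_left <- nfl %/% 2L
    left <- if (n_left > 0L)
      sort(as.integer(round(runif(n_left, lnc_start[r] - 240000L,
                                  lnc_start[r] - 10000L)))) else integer(0)
    right <- if (nfl - n_left > 0L)
      sort(as.integer(round(runif(nfl - n_left, lnc_end[r] + 110000L,
                                  lnc_end[r] + 240000L)))) else integer(0)
    g_inside <- as.integer(round(seq(gene_start[r] + 1000L,
                                     gene_end[r] - 1000L, length.out = spr)))
    pos <- c(left, inside, right, g_inside)
    n_block <- length(pos)
    ids <- sprintf("snp_%s_%02d", lnc_ids[r], seq_len(n_block))
    panel_rows[[r]] <- data.frame(
      snp_id = ids, chrom = chrom_of[r], pos = pos,
      allele_a = "A", allele_b = "B"
    )
    freqs <- runif(n_block, config$maf_range[1], config$maf_range[2])
    hap_blocks[[r]] <- simulate_haplotypes(freqs, 2L * ns, config$ld_block_rho)
    colnames(hap_blocks[[r]]) <- ids
    flank_idx <- c(seq_along(left), length(left) + spr + seq_along(right))
    region_snps[[r]] <- ids[length(left) + seq_len(spr)]
    gene_snps[[r]] <- ids[n_block - spr + seq_len(spr)]
    flank_snps[[r]] <- ids[flank_idx]
  }
  panel <- do.call(rbind, panel_rows)
  rownames(panel) <- NULL
  haps <- do.call(cbind, hap_blocks)
  n_snps <- ncol(haps)

  hap1 <- haps[2L * seq_len(ns) - 1L, , drop = FALSE]
  hap2 <- haps[2L * seq_len(ns), , drop = FALSE]

  # gross HWE violations: force every sample heterozygous at a few SNPs
  n_hwe_bad <- round(config$frac_hwe_bad_snps * n_snps)
  hwe_bad <- if (n_hwe_bad > 0L) sample.int(n_snps, n_hwe_bad) else integer(0)
  hap1[, hwe_bad] <- 0L
  hap2[, hwe_bad] <- 1L
  rownames(hap1) <- rownames(hap2) <- sample_ids

  # --- truth assignment ----------------------------------------------------
  true_rsnp <- rep(NA_character_, nr)
  for (r in eff_idx) {
    cand <- c(region_snps[[r]], flank_snps[[r]])
    cand <- setdiff(cand, colnames(hap1)[hwe_bad])
    true_rsnp[r] <- sample(cand, 1L)
  }

  # --- gDNA genotype calls -------------------------------------------------
  dosage_b <- hap1 + hap2
  geno_str <- matrix(c("AA", "AB", "BB")[dosage_b + 1L], ns, n_snps,
                     dimnames = list(sample_ids, colnames(hap1)))
  n_lowcall <- round(config$frac_lowcall_snps * n_snps)
  lowcall <- if (n_lowcall > 0L)
    sample(setdiff(seq_len(n_snps), hwe_bad), n_lowcall) else integer(0)
  miss_p <- matrix(config$call_missing_rate, ns, n_snps)
  miss_p[, lowcall] <- 0.05
  genotypes <- geno_str
  genotypes[matrix(runif(ns * n_snps), ns, n_snps) < miss_p] <- NA_character_

  # --- cDNA genotype calls (for the contamination filter) ------------------
  call_p <- runif(ns, config$cdna_call_range[1], config$cdna_call_range[2])
  contaminated <- head(sample_ids, config$n_contaminated)
  call_p[sample_ids %in% contaminated] <- 0.6
  cdna_calls <- geno_str
  cdna_calls[matrix(runif(ns * n_snps), ns, n_snps) >=
               matrix(call_p, ns, n_snps)] <- NA_character_

  # --- intensities ---------------------------------------------------------
  frac_a_true <- (2L - dosage_b) / 2          # allele-A dosage fraction
  lnc_expr_log <- rnorm(nr, config$intensity_log_mean, config$intensity_log_sd)
  gene_expr_log <- rnorm(nr, config$intensity_log_mean, config$intensity_log_sd)

  cdna_log_mean <- matrix(config$flank_log_mean, ns, n_snps,
                          dimnames = dimnames(geno_str))
  frac_hap1_cdna <- matrix(0.5, ns, n_snps, dimnames = dimnames(geno_str))
  eff <- config$het_cdna_fraction_under_effect
  for (r in seq_len(nr)) {
    cdna_log_mean[, region_snps[[r]]] <- lnc_expr_log[r]
    g_mean <- gene_expr_log[r]
    if (gene_mode[r] %in% c("co_regulated", "lnc_only", "unknown")) {
      dos <- dosage_b[, true_rsnp[r]]
      cdna_log_mean[, gene_snps[[r]]] <-
        g_mean + config$coexpr_log_slope * (dos - 1)
    } else {
      cdna_log_mean[, gene_snps[[r]]] <- g_mean
    }
    if (!is.na(true_rsnp[r])) {
      h1 <- hap1[, true_rsnp[r]]
      h2 <- hap2[, true_rsnp[r]]
      het <- h1 != h2
      # haplotype carrying allele B at the cis-rSNP is overexpressed
      fr_h1 <- ifelse(het, ifelse(h1 == 1L, eff, 1 - eff), 0.5)
      ase_cols <- if (gene_mode[r] == "co_regulated")
        c(region_snps[[r]], gene_snps[[r]]) else region_snps[[r]]
      frac_hap1_cdna[, ase_cols] <- fr_h1
    }
  }

  gdna_total <- matrix(rlnorm(ns * n_snps, config$gdna_log_mean,
                              config$gdna_log_sd), ns, n_snps)
  cdna_total <- matrix(rlnorm(ns * n_snps, as.vector(cdna_log_mean),
                              config$within_region_log_sd), ns, n_snps)

  # observed allele-A fractions: truth + noise, clipped to [0, 1]
  clip01 <- function(m) pmin(pmax(m, 0), 1)
  gdna_frac <- clip01(frac_a_true + matrix(rnorm(ns * n_snps, 0, config$noise_sd),
                                           ns, n_snps))
  het_mask <- hap1 != hap2
  frac_a_cdna <- frac_a_true
  frac_a_cdna[het_mask] <- ifelse(hap1[het_mask] == 0L,
                                  frac_hap1_cdna[het_mask],
                                  1 - frac_hap1_cdna[het_mask])
  cdna_frac <- clip01(frac_a_cdna + matrix(rnorm(ns * n_snps, 0, config$noise_sd),
                                           ns, n_snps))

  bias <- function(total) {
    L <- log10(total)
    config$dye_bias_coeffs[1] + config$dye_bias_coeffs[2] * L +
      config$dye_bias_coeffs[3] * L^2
  }
  make_channels <- function(total, frac) {
    x <- total * frac * bias(total)
    y <- total * (1 - frac)
    list(x = pmax(x, 0), y = pmax(y, 0))
  }
  g_ch <- make_channels(gdna_total, gdna_frac)
  c_ch <- make_channels(cdna_total, cdna_frac)
  dn <- dimnames(geno_str)
  dimnames(g_ch$x) <- dimnames(g_ch$y) <- dn
  dimnames(c_ch$x) <- dimnames(c_ch$y) <- dn

  # --- peaks ---------------------------------------------------------------
  peaks <- simulate_peaks(panel, true_rsnp, config)

  # --- GWAS catalog --------------------------------------------------------
  rsnp_ids <- true_rsnp[!is.na(true_rsnp)]
  n_mem <- round(config$catalog_fraction * length(rsnp_ids))
  members <- if (n_mem > 0L) sample(rsnp_ids, n_mem) else character(0)
  decoy_pool <- setdiff(panel$snp_id, rsnp_ids)
  decoys <- sample(decoy_pool, min(config$n_catalog_decoys, length(decoy_pool)))
  catalog <- data.frame(
    snp_id = c(members, decoys),
    trait = sprintf("trait_%03d", seq_len(length(members) + length(decoys))),
    immune_related = c(
      runif(length(members)) < config$immune_prob_member,
      runif(length(decoys)) < config$immune_prob_decoy
    )
  )

  truth <- data.frame(
    region_id = lnc_ids,
    true_cis_rsnp_id = true_rsnp,
    het_cdna_fraction = ifelse(is.na(true_rsnp), 0.5, eff),
    gene_id = gene_ids,
    gene_mode = gene_mode,
    co_regulated_gene = gene_mode == "co_regulated",
    catalog_member = !is.na(true_rsnp) & true_rsnp %in% members
  )

  structure(
    list(panel = panel, regions = regions,
         phased = list(hap1 = hap1, hap2 = hap2),
         genotypes = genotypes, cdna_calls = cdna_calls,
         gdna_x = g_ch$x, gdna_y = g_ch$y,
         cdna_x = c_ch$x, cdna_y = c_ch$y,
         peaks = peaks, catalog = catalog, truth = truth,
         config = config),
    class = "ase_bundle"
  )
}

#' Simulate replicate ChIP-seq peak sets
#'
#' Background peaks are placed uniformly over the simulated genome; each
#' true cis-rSNP is additionally covered by a peak with probability
#' `peak_enrichment_odds` times the background coverage rate. Every placed
#' peak is emitted into each of 4 replicates independently with probability
#' `peak_replicate_prob`, with jittered boundaries and a peak-calling
#' p-value below the consensus threshold (a small fraction get weak
#' p-values and are dropped by the consensus step).
#'
#' @param panel SNP panel data.frame.
#' @param true_rsnp True cis-rSNP ids (`NA` entries ignored).
#' @param config A [simulation_config()].
#' @return List of 4 `GRanges`, one per replicate, with `mark`,
#'   `replicate_id`, `peak_p` columns.
#' @export
simulate_peaks <- function(panel, true_rsnp, config) {
  chroms <- sort(unique(panel$chrom))
  span <- vapply(chroms, function(ch) max(panel$pos[panel$chrom == ch]) + 250000L, 0)
  genome_bp <- sum(span)
  w <- config$peak_width
  base_rate <- config$n_bg_peaks_per_mark * w / genome_bp
  p_cover <- min(1, config$peak_enrichment_odds * base_rate)
  rsnp_ids <- true_rsnp[!is.na(true_rsnp)]
  rsnp_pos <- panel[match(rsnp_ids, panel$snp_id), c("chrom", "pos")]

  place_mark <- function(mark) {
    n_bg <- config$n_bg_peaks_per_mark
    bg_chrom <- sample(chroms, n_bg, replace = TRUE, prob = span / genome_bp)
    bg_center <- floor(runif(n_bg, 1, span[match(bg_chrom, chroms)]))
    covered <- runif(nrow(rsnp_pos)) < p_cover
    center <- c(bg_center,
                rsnp_pos$pos[covered] + round(runif(sum(covered), -w / 4, w / 4)))
    chrom <- c(bg_chrom, rsnp_pos$chrom[covered])
    data.frame(chrom = chrom, center = center, mark = mark)
  }
  placed <- rbind(place_mark("H3K27ac"), place_mark("H3K4me1"))

  lapply(1:4, function(rep_i) {
    emit <- runif(nrow(placed)) < config$peak_replicate_prob
    sub <- placed[emit, , drop = FALSE]
    jitter <- function(n) round(rnorm(n, 0, config$peak_jitter_sd))
    start1 <- pmax(1L, sub$center - w %/% 2L + jitter(nrow(sub)))
    end1 <- pmax(start1 + 1L, sub$center + w %/% 2L + jitter(nrow(sub)))
    peak_p <- 10^(-runif(nrow(sub), 5.5, 12))
    weak <- runif(nrow(sub)) < 0.05
    peak_p[weak] <- 10^(-runif(sum(weak), 2, 4.5))
    gr <- GRanges(sub$chrom, IRanges(start1, end1))
    mcols(gr)$mark <- sub$mark
    mcols(gr)$replicate_id <- sprintf("rep%d", rep_i)
    mcols(gr)$peak_p <- peak_p
    gr
  })
}

#' Write a synthetic bundle to a directory of plain-text files
#'
#' File names match what [read_bundle()] expects: `panel.tsv`,
#' `regions.bed`, `phased.tsv`, `genotypes.tsv`, `cdna_calls.tsv`,
#' `{gdna,cdna}_{x,y}.tsv`, `peaks_rep[1-4].bed`, `gwas_catalog.tsv`,
#' `truth_table.tsv`, `config.yaml`.
#'
#' @param bundle An `ase_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_snp_panel(bundle$panel, fp("panel.tsv"))
  write_regions(bundle$regions, fp("regions.bed"))
  write_phased(bundle$phased, fp("phased.tsv"))
  write_matrix(bundle$genotypes, fp("genotypes.tsv"))
  write_matrix(bundle$cdna_calls, fp("cdna_calls.tsv"))
  for (nm in c("gdna_x", "gdna_y", "cdna_x", "cdna_y")) {
    write_matrix(round(bundle[[nm]], 4), fp(paste0(nm, ".tsv")))
  }
  for (i in seq_along(bundle$peaks)) {
    write_peaks(bundle$peaks[[i]], fp(sprintf("peaks_rep%d.bed", i)))
  }
  write_gwas_catalog(bundle$catalog, fp("gwas_catalog.tsv"))
  fwrite(as.data.table(bundle$truth), fp("truth_table.tsv"), sep = "\t",
         na = "NA", quote = FALSE)
  cfg <- unclass(bundle$config)
  yaml::write_yaml(cfg, fp("config.yaml"))
  invisible(dir)
}

#' Read a bundle back from a directory
#' @param dir Directory written by [write_bundle()].
#' @return An `ase_bundle` (truth and config included when present).
#' @export
read_bundle <- function(dir) {
  fp <- function(f) file.path(dir, f)
  panel <- read_snp_panel(fp("panel.tsv"))
  peaks <- list()
  i <- 1L
  while (file.exists(fp(sprintf("peaks_rep%d.bed", i)))) {
    peaks[[i]] <- read_peaks(fp(sprintf("peaks_rep%d.bed", i)))
    i <- i + 1L
  }
  truth <- if (file.exists(fp("truth_table.tsv"))) {
    as.data.frame(fread(fp("truth_table.tsv"), sep = "\t"))
  } else NULL
  structure(
    list(panel = panel,
         regions = read_regions(fp("regions.bed")),
         phased = read_phased(fp("phased.tsv"), panel),
         genotypes = read_matrix(fp("genotypes.tsv"), panel, numeric = FALSE),
         cdna_calls = read_matrix(fp("cdna_calls.tsv"), panel, numeric = FALSE),
         gdna_x = read_matrix(fp("gdna_x.tsv"), panel),
         gdna_y = read_matrix(fp("gdna_y.tsv"), panel),
         cdna_x = read_matrix(fp("cdna_x.tsv"), panel),
         cdna_y = read_matrix(fp("cdna_y.tsv"), panel),
         peaks = peaks,
         catalog = read_gwas_catalog(fp("gwas_catalog.tsv")),
         truth = truth,
         config = NULL),
    class = "ase_bundle"
  )
}
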