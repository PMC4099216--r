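#' Per-SNP allele-specific expression level
#'
#' ASE at a heterozygous SNP is the difference between the normalized cDNA
#' and gDNA allele fractions of the allele carried on haplotype 1:
#' `cdna_fraction - gdna_fraction`. The per-sample gDNA fraction (not a
#' fixed 0.5) serves as the quantification standard, absorbing residual
#' probe bias. Vectorized.
#'
#' @param cdna_fraction,gdna_fraction Phase-oriented adjusted allele
#'   fractions (fraction of the haplotype-1 allele).
#' @return Signed ASE level in `[-1, 1]`.
#' @export
snp_ase <- function(cdna_fraction, gdna_fraction) {
  cdna_fraction - gdna_fraction
}

#' Phase-orient an allele-A fraction
#'
#' Allele fractions are computed on allele A (the x channel). Within a
#' region all per-SNP signals must refer to the same chromosome, so at SNPs
#' whose haplotype-1 allele is B the fraction is flipped to `1 - f`.
#'
#' @param frac_a Allele-A fraction.
#' @param hap1_allele 0 (allele A on haplotype 1) or 1 (allele B).
#' @return Fraction of the haplotype-1 allele.
#' @export
orient_fraction <- function(frac_a, hap1_allele) {
  ifelse(hap1_allele == 1L, 1 - frac_a, frac_a)
}

#' Sample-by-SNP matrix of phase-oriented ASE levels
#'
#' ASE is computed only where the gDNA call is heterozygous and both
#' adjusted fractions and the phase are available; everywhere else the entry
#' is `NA` (homozygous SNPs are excluded, never set to 0).
#'
#' @param gdna_frac,cdna_frac Adjusted allele-A fraction matrices.
#' @param gdna_calls gDNA genotype call matrix (`"AA"/"AB"/"BB"`/NA).
#' @param hap1 Haplotype-1 allele matrix (0/1/NA) from [read_phased()].
#' @return Matrix of signed per-SNP ASE levels (NA where not computable).
#' @export
ase_snp_matrix <- function(gdna_frac, cdna_frac, gdna_calls, hap1) {
  stopifnot(all(dim(gdna_frac) == dim(cdna_frac)),
            all(dim(gdna_frac) == dim(gdna_calls)),
            all(dim(gdna_frac) == dim(hap1)))
  het <- !is.na(gdna_calls) & gdna_calls == "AB" & !is.na(hap1)
  g <- orient_fraction(gdna_frac, hap1)
  c_ <- orient_fraction(cdna_frac, hap1)
  out <- snp_ase(c_, g)
  out[!het] <- NA_real_
  out
}

#' SNP ids located within a region
#' @param region A length-1 `GRanges` region.
#' @param panel SNP panel data.frame.
#' @return Character vector of SNP ids whose 1-based position lies in the
#'   region's 1-based inclusive span.
#' @export
snps_in_region <- function(region, panel) {
  stopifnot(length(region) == 1L)
  sel <- panel$chrom == as.character(seqnames(region)) &
    panel$pos >= start(region) & panel$pos <= end(region)
  panel$snp_id[sel]
}

#' Total-expression level of a region
#'
#' The sum of the raw two-channel cDNA signals at a SNP measures total
#' expression at that position; the region's expression level is the mean of
#' these sums over the region's SNPs and over all samples.
#'
#' @param cdna_x,cdna_y Raw cDNA intensity matrices.
#' @param snp_ids SNP ids of the region.
#' @return Mean fluorescence-unit expression (0 if no data).
#' @export
expression_level <- function(cdna_x, cdna_y, snp_ids) {
  snp_ids <- intersect(snp_ids, colnames(cdna_x))
  if (length(snp_ids) == 0L) return(0)
  s <- cdna_x[, snp_ids, drop = FALSE] + cdna_y[, snp_ids, drop = FALSE]
  if (all(is.na(s))) return(0)
  mean(s, na.rm = TRUE)
}

#' Expression filter
#' @param mean_expression Region expression from [expression_level()].
#' @param thresh Minimum acceptable mean signal (fluorescence units,
#'   inclusive; default 1000).
#' @return TRUE iff the region counts as expressed.
#' @export
expression_filter <- function(mean_expression, thresh = 1000) {
  mean_expression >= thresh
}

#' Per-sample window ASE for one region
#'
#' The window ASE of a sample is the arithmetic mean of its heterozygous-SNP
#' ASE levels within the region; samples with no heterozygous SNP in the
#' region get `NA`. The region is informative iff at least
#' `min_informative` distinct SNP positions carry an ASE value in at least
#' one sample each.
#'
#' @param snp_ids SNP ids of the region.
#' @param ase Sample-by-SNP ASE matrix from [ase_snp_matrix()].
#' @param min_informative Minimum informative SNP positions (default 3).
#' @return A list with per-sample `ase`, `n_informative`, and `informative`.
#' @export
window_ase <- function(snp_ids, ase, min_informative = 3L) {
  snp_ids <- intersect(snp_ids, colnames(ase))
  sub <- ase[, snp_ids, drop = FALSE]
  informative_snps <- snp_ids[colSums(!is.na(sub)) > 0L]
  n_inf <- length(informative_snps)
  w <- rowMeans(sub[, informative_snps, drop = FALSE], na.rm = TRUE)
  w[!is.finite(w)] <- NA_real_
  list(ase = w, n_informative = n_inf,
       informative = n_inf >= min_informative)
}

#' Compute all ASE windows
#'
#' Applies [window_ase()], [expression_level()] and [expression_filter()] to
#' every region and reports the filter funnel. A region passes iff it has at
#' least `ase.min_informative_snps` informative SNP positions and its mean
#' expression is at least `ase.expression_threshold`.
#'
#' @param regions Region `GRanges` from [read_regions()].
#' @param panel SNP panel data.frame.
#' @param ase Sample-by-SNP ASE matrix from [ase_snp_matrix()].
#' @param cdna_x,cdna_y Raw cDNA intensity matrices (for expression).
#' @param config Configuration list.
#' @return A list with `summary` (one row per region: `region_id`,
#'   `region_class`, `n_informative_snps`, `mean_expression`,
#'   `informative`, `expressed`, `passed`) and `ase` (region-by-sample
#'   matrix of window ASE levels, rows = passing regions only).
#' @export
compute_ase_windows <- function(regions, panel, ase, cdna_x, cdna_y,
                                config = default_config()) {
  n <- length(regions)
  region_id <- mcols(regions)$region_id
  summary <- data.frame(
    region_id = region_id,
    region_class = mcols(regions)$region_class,
    n_informative_snps = integer(n),
    mean_expression = numeric(n),
    informative = logical(n),
    expressed = logical(n),
    passed = logical(n)
  )
  rows <- list()
  for (i in seq_len(n)) {
    ids <- snps_in_region(regions[i], panel)
    if (length(ids) == 0L) {
      summary$n_informative_snps[i] <- 0L
      next
    }
    w <- window_ase(ids, ase, config$ase.min_informative_snps)
    expr <- expression_level(cdna_x, cdna_y, ids)
    summary$n_informative_snps[i] <- w$n_informative
    summary$mean_expression[i] <- expr
    summary$informative[i] <- w$informative
    summary$expressed[i] <- expression_filter(expr, config$ase.expression_threshold)
    summary$passed[i] <- summary$informative[i] && summary$expressed[i]
    if (summary$passed[i]) rows[[region_id[i]]] <- w$ase
  }
  ase_mat <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    matrix(numeric(0), 0L, nrow(ase), dimnames = list(NULL, rownames(ase)))
  }
  list(summary = summary, ase = ase_mat)
}

#' Write the ASE-window result table
#' @param windows Result of [compute_ase_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ase_windows <- function(windows, path) {
  dt <- as.data.table(windows$summary)
  if (nrow(windows$ase) > 0L) {
    ase_dt <- as.data.table(windows$ase, keep.rownames = "region_id")
    dt <- merge(dt, ase_dt, by = "region_id", all.x = TRUE, sort = FALSE)
  }
  fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
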