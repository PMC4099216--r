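#' SNP and sample call-rate filter
#'
#' A SNP is retained iff its non-missing call fraction is at least
#' `snp_thresh` (default 99%); the SNP filter is applied first and samples
#' are then filtered at `sample_thresh` (default 98%) on the retained SNPs.
#' Both thresholds are inclusive.
#'
#' @param genotypes Sample-by-SNP character matrix of genotype calls
#'   (`"AA"`, `"AB"`, `"BB"`, `NA` = no call).
#' @param snp_thresh,sample_thresh Minimum call-rate fractions.
#' @return A list with character vectors `snps` and `samples` of retained ids.
#' @export
call_rate_filter <- function(genotypes, snp_thresh = 0.99, sample_thresh = 0.98) {
  stopifnot(nrow(genotypes) > 0L, ncol(genotypes) > 0L)
  snp_cr <- colMeans(!is.na(genotypes))
  keep_snps <- snp_cr >= snp_thresh
  sub <- genotypes[, keep_snps, drop = FALSE]
  if (ncol(sub) == 0L) {
    keep_samples <- rep(TRUE, nrow(genotypes))
  } else {
    keep_samples <- rowMeans(!is.na(sub)) >= sample_thresh
  }
  list(snps = colnames(genotypes)[keep_snps],
       samples = rownames(genotypes)[keep_samples])
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Plain 1-df chi-square (no continuity correction) of the observed genotype
#' counts against the expectation p^2 : 2pq : q^2 under the allele
#' frequencies estimated from the same counts. A monomorphic SNP (one allele
#' absent) returns chi2 = 0, p = 1 by convention. Invariant under swapping
#' the two homozygote counts.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (sum > 0).
#' @return A list with `chi2` and `p`.
#' @export
hwe_chisq <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  stopifnot(n > 0)
  p_a <- (2 * n_aa + n_ab) / (2 * n)
  if (p_a == 0 || p_a == 1) {
    return(list(chi2 = 0, p = 1))
  }
  expected <- n * c(p_a^2, 2 * p_a * (1 - p_a), (1 - p_a)^2)
  chi2 <- sum((c(n_aa, n_ab, n_bb) - expected)^2 / expected)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' HWE p-values for every SNP of a genotype matrix
#' @param genotypes Sample-by-SNP genotype call matrix.
#' @return Named numeric vector of HWE p-values (one per SNP).
#' @export
hwe_pvalues <- function(genotypes) {
  vapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    n_aa <- sum(g == "AA", na.rm = TRUE)
    n_ab <- sum(g == "AB", na.rm = TRUE)
    n_bb <- sum(g == "BB", na.rm = TRUE)
    if (n_aa + n_ab + n_bb == 0L) return(1)
    hwe_chisq(n_aa, n_ab, n_bb)$p
  }, 0, USE.NAMES = FALSE) |> setNames(colnames(genotypes))
}

#' cDNA contamination filter
#'
#' In cDNA most SNPs fail genotype calling because only expressed
#' transcripts give signal; a sample whose cDNA call rate is *strictly*
#' above `thresh` (default 40%) looks like genomic DNA and is flagged as
#' possibly contaminated.
#'
#' @param cdna_calls Sample-by-SNP cDNA genotype call matrix (NA = no call).
#' @param thresh Call-rate fraction above which a sample is flagged.
#' @return Character vector of flagged sample ids.
#' @export
contamination_filter <- function(cdna_calls, thresh = 0.40) {
  cr <- rowMeans(!is.na(cdna_calls))
  rownames(cdna_calls)[cr > thresh]
}

#' Run the full pre-ASE quality control
#'
#' Order: SNP call-rate filter, sample call-rate filter, HWE filter on the
#' call-rate-retained data, then the cDNA contamination filter on the
#' surviving samples. Applying the QC twice changes nothing.
#'
#' @param genotypes gDNA genotype call matrix.
#' @param cdna_calls cDNA genotype call matrix (same shape).
#' @param config Configuration list (see [default_config()]).
#' @return A list with retained `snps`, retained `samples`, and a one-row
#'   `report` data.frame of per-category removal counts.
#' @export
run_qc <- function(genotypes, cdna_calls, config = default_config()) {
  cr <- call_rate_filter(genotypes,
                         snp_thresh = config$qc.snp_call_rate,
                         sample_thresh = config$qc.sample_call_rate)
  sub <- genotypes[cr$samples, cr$snps, drop = FALSE]
  hwe_p <- hwe_pvalues(sub)
  keep_snps <- names(hwe_p)[hwe_p >= config$qc.hwe_p]
  contaminated <- contamination_filter(
    cdna_calls[cr$samples, keep_snps, drop = FALSE],
    thresh = config$qc.contamination_call_rate
  )
  keep_samples <- setdiff(cr$samples, contaminated)
  report <- data.frame(
    snps_removed_callrate = ncol(genotypes) - length(cr$snps),
    snps_removed_hwe = length(cr$snps) - length(keep_snps),
    samples_removed_callrate = nrow(genotypes) - length(cr$samples),
    samples_removed_contamination = length(contaminated)
  )
  list(snps = keep_snps, samples = keep_samples, report = report)
}
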