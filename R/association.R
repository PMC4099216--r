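#' Candidate SNPs for a region
#'
#' All panel SNPs on the region's chromosome whose 1-based position lies
#' within `window_bp` of the region (inclusive at both boundaries), SNPs
#' inside the region included.
#'
#' @param region A length-1 `GRanges` region.
#' @param panel SNP panel data.frame.
#' @param window_bp Flank size in bp (default 250 kb).
#' @return Character vector of candidate SNP ids.
#' @export
candidate_snps <- function(region, panel, window_bp = 250000L) {
  stopifnot(length(region) == 1L)
  lo <- start(region) - window_bp
  hi <- end(region) + window_bp
  sel <- panel$chrom == as.character(seqnames(region)) &
    panel$pos >= lo & panel$pos <= hi
  panel$snp_id[sel]
}

#' Phased genotype code for the association test
#'
#' Homozygotes (AA and BB) form one group with expected window ASE near
#' zero and are coded 0. Heterozygotes split by phase: allele A on
#' haplotype 1 codes +1, allele B on haplotype 1 codes -1 -- under a true
#' cis effect the two heterozygote orientations acquire window ASE of
#' opposite sign. Missing genotypes return `NA` (the sample drops out of
#' the test). Vectorized.
#'
#' @param hap1,hap2 Haplotype alleles (0 = A, 1 = B, NA = missing).
#' @return Integer code in `{-1, 0, +1}` or `NA`.
#' @export
genotype_code <- function(hap1, hap2) {
  code <- rep(NA_integer_, length(hap1))
  ok <- !is.na(hap1) & !is.na(hap2)
  hom <- ok & hap1 == hap2
  code[hom] <- 0L
  code[ok & hap1 == 0L & hap2 == 1L] <- 1L
  code[ok & hap1 == 1L & hap2 == 0L] <- -1L
  code
}

#' Linear regression of window ASE on genotype codes
#'
#' Ordinary least squares of `ase = alpha + beta * code` with a two-sided
#' t-test on the slope (n - 2 df), computed in closed form. Samples with a
#' missing code or ASE value are dropped. Degenerate cases follow fixed
#' conventions: all-equal codes give `NA` (test skipped); zero residual
#' variance with a nonzero slope reports the smallest representable
#' positive p; a zero slope with zero residual variance reports p = 1.
#'
#' @param codes Per-sample genotype codes in `{-1, 0, +1}`.
#' @param ase Per-sample window ASE levels.
#' @return A list with `slope`, `p_value`, `n`, and per-class counts
#'   `n_ab` (+1), `n_ba` (-1), `n_hom` (0).
#' @export
ase_regression <- function(codes, ase) {
  stopifnot(length(codes) == length(ase))
  ok <- !is.na(codes) & !is.na(ase)
  x <- as.numeric(codes[ok])
  y <- ase[ok]
  n <- length(x)
  counts <- c(n_ab = sum(x == 1), n_ba = sum(x == -1), n_hom = sum(x == 0))
  if (n < 3L || length(unique(x)) < 2L) {
    return(c(list(slope = NA_real_, p_value = NA_real_, n = n), as.list(counts)))
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  slope <- sum(xc * yc) / sxx
  rss <- sum((yc - slope * xc)^2)
  if (rss <= 0) {
    p <- if (slope == 0) 1 else .Machine$double.xmin
    return(c(list(slope = slope, p_value = p, n = n), as.list(counts)))
  }
  se <- sqrt(rss / (n - 2L) / sxx)
  tstat <- slope / se
  p <- 2 * pt(abs(tstat), df = n - 2L, lower.tail = FALSE)
  c(list(slope = slope, p_value = p, n = n), as.list(counts))
}

#' Significance filter for an association result
#'
#' A (region, SNP) association is significant iff `p < p_thresh`,
#' `|slope| >= slope_thresh`, and each allele combination has enough data
#' points: at least `min_per_class` samples in the AB class, in the BA
#' class, and among pooled homozygotes. The slope threshold excludes
#' biologically small effects (0.05 corresponds to about a 20% expression
#' difference between alleles); the count rule guards against inflated
#' p-values from tiny classes.
#'
#' @param p_value,slope,n_ab,n_ba,n_hom Association results (vectorized).
#' @param p_thresh,slope_thresh,min_per_class Thresholds (defaults 1e-6,
#'   0.05, 4).
#' @return Logical: significant or not (`FALSE` where the test is missing).
#' @export
significance_filter <- function(p_value, slope, n_ab, n_ba, n_hom,
                                p_thresh = 1e-6, slope_thresh = 0.05,
                                min_per_class = 4L) {
  sig <- !is.na(p_value) & !is.na(slope) &
    p_value < p_thresh & abs(slope) >= slope_thresh &
    n_ab >= min_per_class & n_ba >= min_per_class & n_hom >= min_per_class
  sig
}

#' Haplotype linkage disequilibrium r-squared
#'
#' `r^2 = D^2 / (pA (1-pA) pB (1-pB))` with `D = pAB - pA pB`, computed on
#' paired binary haplotype vectors. A monomorphic locus makes r^2
#' undefined (`NA`).
#'
#' @param hapA,hapB Binary (0/1) haplotype vectors of equal length >= 2.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(hapA, hapB) {
  stopifnot(length(hapA) == length(hapB), length(hapA) >= 2L)
  ok <- !is.na(hapA) & !is.na(hapB)
  a <- hapA[ok]
  b <- hapB[ok]
  pA <- mean(a)
  pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  D <- mean(a * b) - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  min(r2, 1)
}

#' Convert a window-ASE slope to a percent expression difference
#'
#' A slope `s` means the two alleles of a heterozygote are expressed at
#' fractions `0.5 + s` and `0.5 - s` of the transcript pool; the percent
#' difference relative to their mean is `100 * 2s / 0.5 = 400 * s`. The
#' published slope threshold 0.05 therefore corresponds to about a 20%
#' expression difference between alleles.
#'
#' @param slope Nonnegative ASE slope (values >= 0.5 are capped with a
#'   warning: the minor allele fraction cannot go below zero).
#' @return Percent expression difference between the two alleles.
#' @export
slope_to_percent_diff <- function(slope) {
  stopifnot(all(slope >= 0))
  if (any(slope >= 0.5)) {
    warning("slope >= 0.5 capped at 0.5 (allele fraction bound)")
    slope <- pmin(slope, 0.5)
  }
  400 * slope
}

#' Greedy LD pruning
#'
#' Returns a subset of SNPs no two of which have r^2 above `r2_thresh`,
#' scanning in panel order and dropping any SNP in high LD with an already
#' kept one. The size of the pruned set is an effective test count for
#' users who want to re-derive a multiple-testing threshold; it does not
#' change the published default of 1e-6.
#'
#' @param haps 2n-by-SNP binary haplotype matrix (columns = SNPs).
#' @param r2_thresh LD threshold (default 0.9).
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(haps, r2_thresh = 0.9) {
  ids <- colnames(haps)
  kept <- character(0)
  kept_idx <- integer(0)
  for (j in seq_len(ncol(haps))) {
    high <- FALSE
    for (k in kept_idx) {
      r2 <- ld_r2(haps[, k], haps[, j])
      if (!is.na(r2) && r2 > r2_thresh) {
        high <- TRUE
        break
      }
    }
    if (!high) {
      kept <- c(kept, ids[j])
      kept_idx <- c(kept_idx, j)
    }
  }
  kept
}

#' Test every candidate SNP against every ASE window
#'
#' For each passing region and each candidate SNP within the window, samples
#' with both a window ASE value and a nonmissing phased genotype enter an
#' [ase_regression()]; results are filtered with [significance_filter()].
#'
#' @param regions Region `GRanges` (only ids present in `windows$ase` rows
#'   are tested).
#' @param windows Result of [compute_ase_windows()].
#' @param panel SNP panel data.frame.
#' @param phased List with `hap1`, `hap2` matrices (QC-retained samples).
#' @param config Configuration list.
#' @return A data.frame: `region_id`, `snp_id`, `distance_bp`, `slope`,
#'   `p_value`, `n_ab`, `n_ba`, `n_hom`, `significant`.
#' @export
test_associations <- function(regions, windows, panel, phased,
                              config = default_config()) {
  panel_pos <- setNames(panel$pos, panel$snp_id)
  out <- list()
  tested_ids <- rownames(windows$ase)
  samples <- colnames(windows$ase)
  hap1 <- phased$hap1[samples, , drop = FALSE]
  hap2 <- phased$hap2[samples, , drop = FALSE]
  for (rid in tested_ids) {
    region <- regions[mcols(regions)$region_id == rid]
    cands <- intersect(candidate_snps(region, panel, config$assoc.window_bp),
                       colnames(hap1))
    if (length(cands) == 0L) next
    ase <- windows$ase[rid, ]
    res <- lapply(cands, function(sid) {
      codes <- genotype_code(hap1[, sid], hap2[, sid])
      r <- ase_regression(codes, ase)
      pos <- panel_pos[[sid]]
      dist <- max(0L, start(region) - pos, pos - end(region))
      data.frame(region_id = rid, snp_id = sid, distance_bp = dist,
                 slope = r$slope, p_value = r$p_value,
                 n_ab = r$n_ab, n_ba = r$n_ba, n_hom = r$n_hom)
    })
    out[[rid]] <- do.call(rbind, res)
  }
  if (length(out) == 0L) {
    return(data.frame(region_id = character(0), snp_id = character(0),
                      distance_bp = integer(0), slope = numeric(0),
                      p_value = numeric(0), n_ab = integer(0),
                      n_ba = integer(0), n_hom = integer(0),
                      significant = logical(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$significant <- significance_filter(
    res$p_value, res$slope, res$n_ab, res$n_ba, res$n_hom,
    p_thresh = config$assoc.p_thresh,
    slope_thresh = config$assoc.slope_thresh,
    min_per_class = config$assoc.min_per_class
  )
  res
}
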