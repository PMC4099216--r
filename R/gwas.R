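#' Overlap significant cis-rSNPs with a GWAS catalog
#'
#' A catalog SNP overlaps a region's cis-rSNP set either directly (same
#' rsID; reported with `ld_r2 = 1`) or as an LD proxy: some significant
#' cis-rSNP of the region has `r^2 >= r2_thresh` with it on the provided
#' haplotypes. One record is emitted per (region, catalog SNP, trait);
#' catalog SNPs absent from the haplotype panel are skipped for the proxy
#' search.
#'
#' @param associations Association table from [test_associations()].
#' @param catalog GWAS-catalog data.frame from [read_gwas_catalog()].
#' @param haps 2n-by-SNP binary haplotype matrix (columns = panel SNPs).
#' @param r2_thresh Proxy LD threshold (default 0.8).
#' @return data.frame: `region_id`, `cis_rsnp_id`, `catalog_snp_id`,
#'   `ld_r2`, `trait`, `immune_related`.
#' @export
overlap_catalog <- function(associations, catalog, haps, r2_thresh = 0.8) {
  sig <- associations[associations$significant, , drop = FALSE]
  out <- list()
  for (rid in unique(sig$region_id)) {
    rsnps <- sig$snp_id[sig$region_id == rid]
    for (k in seq_len(nrow(catalog))) {
      cat_snp <- catalog$snp_id[k]
      if (cat_snp %in% rsnps) {
        hit <- list(cis = cat_snp, r2 = 1.0)
      } else if (cat_snp %in% colnames(haps)) {
        r2s <- vapply(rsnps, function(s) {
          if (!s %in% colnames(haps)) return(NA_real_)
          ld_r2(haps[, s], haps[, cat_snp])
        }, 0)
        if (all(is.na(r2s)) || max(r2s, na.rm = TRUE) < r2_thresh) {
          hit <- NULL
        } else {
          best <- which.max(r2s)
          hit <- list(cis = rsnps[best], r2 = r2s[best])
        }
      } else {
        hit <- NULL
      }
      if (!is.null(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          region_id = rid, cis_rsnp_id = hit$cis,
          catalog_snp_id = cat_snp, ld_r2 = hit$r2,
          trait = catalog$trait[k],
          immune_related = catalog$immune_related[k]
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(region_id = character(0), cis_rsnp_id = character(0),
                      catalog_snp_id = character(0), ld_r2 = numeric(0),
                      trait = character(0), immune_related = logical(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate overlaps with their enhancer context
#'
#' For each overlap record, reports whether the cis-rSNP position falls in
#' an H3K4me1 consensus peak, an H3K27ac consensus peak, within the 2.5 kb
#' flanks of either, or none (checked in that order).
#'
#' @param overlaps Overlap table from [overlap_catalog()].
#' @param panel SNP panel data.frame.
#' @param peaks_by_mark Named list of consensus-peak `GRanges` per mark.
#' @param flank_bp Flank size (default 2500).
#' @return `overlaps` with an added `in_peak` column
#'   (`in_H3K4me1` / `in_H3K27ac` / `flank_2.5kb` / `none`).
#' @export
annotate_enhancer_context <- function(overlaps, panel, peaks_by_mark,
                                      flank_bp = 2500L) {
  if (nrow(overlaps) == 0L) {
    overlaps$in_peak <- character(0)
    return(overlaps)
  }
  pos <- snp_granges(panel, overlaps$cis_rsnp_id)
  ctx <- rep("none", nrow(overlaps))
  all_peaks <- suppressWarnings(do.call(c, unname(peaks_by_mark)))
  if (!is.null(all_peaks) && length(all_peaks) > 0L) {
    flanked <- flank_peaks(all_peaks, flank_bp)
    ctx[in_peak(pos, flanked)] <- "flank_2.5kb"
  }
  if (!is.null(peaks_by_mark$H3K27ac)) {
    ctx[in_peak(pos, peaks_by_mark$H3K27ac)] <- "in_H3K27ac"
  }
  if (!is.null(peaks_by_mark$H3K4me1)) {
    ctx[in_peak(pos, peaks_by_mark$H3K4me1)] <- "in_H3K4me1"
  }
  overlaps$in_peak <- ctx
  overlaps
}

#' Immune-trait over-representation test
#'
#' Two-sided Fisher's exact test on the 2x2 table of catalog SNPs
#' cross-classified by "overlapped by a cis-rSNP" and "immune-related
#' trait". A catalog whose traits are all immune or all non-immune makes
#' the test undefined (`NA`).
#'
#' @param overlaps Overlap table from [overlap_catalog()].
#' @param catalog GWAS-catalog data.frame.
#' @return A list with `fisher_p` and the 2x2 `table`.
#' @export
trait_enrichment <- function(overlaps, catalog) {
  cat_u <- unique(catalog[, c("snp_id", "immune_related")])
  if (all(cat_u$immune_related) || !any(cat_u$immune_related)) {
    return(list(fisher_p = NA_real_, table = NULL))
  }
  hit <- cat_u$snp_id %in% overlaps$catalog_snp_id
  tab <- table(overlapped = factor(hit, c(TRUE, FALSE)),
               immune = factor(cat_u$immune_related, c(TRUE, FALSE)))
  list(fisher_p = fisher.test(tab)$p.value, table = tab)
}
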