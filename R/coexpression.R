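#' Genotype-group expression test
#'
#' Samples are split into three groups by the genotype at the most
#' significant cis-rSNP -- AA (code 0), AB/BA pooled (code 1), BB (code 2)
#' -- and the per-sample total expression is regressed on the group code by
#' ordinary least squares, with a two-sided t-test on the slope. Requires
#' at least two represented groups.
#'
#' @param dosage Per-sample allele-B dosage (0, 1, 2; AB and BA pool at 1).
#' @param expression Per-sample mean two-allele raw cDNA intensity.
#' @return A list with `slope`, `p_value`, `n` (or `NA`s if only one group
#'   is represented).
#' @export
genotype_group_expression_test <- function(dosage, expression) {
  stopifnot(length(dosage) == length(expression))
  ok <- !is.na(dosage) & !is.na(expression)
  x <- as.numeric(dosage[ok])
  y <- expression[ok]
  if (length(unique(x)) < 2L || length(x) < 3L) {
    return(list(slope = NA_real_, p_value = NA_real_, n = length(x)))
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  slope <- sum(xc * yc) / sxx
  rss <- sum((yc - slope * xc)^2)
  if (rss <= 0) {
    p <- if (slope == 0) 1 else .Machine$double.xmin
    return(list(slope = slope, p_value = p, n = length(x)))
  }
  se <- sqrt(rss / (length(x) - 2L) / sxx)
  p <- 2 * pt(abs(slope / se), df = length(x) - 2L, lower.tail = FALSE)
  list(slope = slope, p_value = p, n = length(x))
}

#' Allele-B dosage from phased genotypes
#' @param hap1,hap2 Haplotype alleles (0/1/NA).
#' @return Integer dosage 0/1/2 (`NA` where either haplotype is missing).
#' @export
genotype_dosage <- function(hap1, hap2) {
  hap1 + hap2
}

#' Benjamini-Hochberg rejection set
#'
#' Step-up FDR control: with `m` p-values sorted ascending, reject all
#' hypotheses up to the largest `i` with `p(i) <= i*q/m`. Delegates to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Vector of p-values in `(0, 1]`.
#' @param q Target FDR (default 0.10).
#' @return Integer indices (into `p_values`) of rejected hypotheses.
#' @export
bh_fdr <- function(p_values, q = 0.10) {
  if (length(p_values) == 0L) return(integer(0))
  stopifnot(all(p_values > 0 & p_values <= 1))
  which(p.adjust(p_values, method = "BH") <= q)
}

#' Classify a cis-rSNP / lncRNA / protein-coding-gene trio
#'
#' For pairs passing the co-expression FDR: `co_regulated` iff the nearest
#' gene's own ASE association with the same cis-rSNP is significant
#' (p < `ase_p_thresh`); `lnc_only` iff the gene was evaluable but not
#' significant; `unknown` iff the gene's ASE could not be evaluated (no
#' expressed ASE window for it within the candidate window of the SNP).
#'
#' @param gene_ase_p Gene ASE association p-value for the same SNP, or `NA`
#'   when not evaluable.
#' @param ase_p_thresh Significance cutoff (default 1e-6).
#' @return One of `"co_regulated"`, `"lnc_only"`, `"unknown"`.
#' @export
classify_pair <- function(gene_ase_p, ase_p_thresh = 1e-6) {
  if (is.na(gene_ase_p)) return("unknown")
  if (gene_ase_p < ase_p_thresh) "co_regulated" else "lnc_only"
}

#' Nearest protein-coding region for each lncRNA region
#'
#' Minimal boundary-to-boundary distance on the same chromosome (0 for
#' overlap); ties broken by the smaller gene start.
#'
#' @param lnc_regions,gene_regions `GRanges` with `region_id` columns.
#' @return data.frame `region_id`, `gene_id`, `distance_bp` (`NA` gene id
#'   where the chromosome has no gene).
#' @export
nearest_gene <- function(lnc_regions, gene_regions) {
  out <- data.frame(region_id = mcols(lnc_regions)$region_id,
                    gene_id = NA_character_, distance_bp = NA_integer_)
  for (i in seq_along(lnc_regions)) {
    same <- gene_regions[as.character(seqnames(gene_regions)) ==
                           as.character(seqnames(lnc_regions[i]))]
    if (length(same) == 0L) next
    d <- pmax(0L, pmax(start(same) - end(lnc_regions[i]),
                       start(lnc_regions[i]) - end(same)))
    best <- which(d == min(d))
    if (length(best) > 1L) best <- best[which.min(start(same)[best])]
    out$gene_id[i] <- mcols(same)$region_id[best]
    out$distance_bp[i] <- d[best]
  }
  out
}

#' Co-expression and co-regulation analysis
#'
#' For every lncRNA region with at least one significant cis-rSNP, takes
#' the most significant SNP, regresses the nearest protein-coding gene's
#' total expression on the SNP's genotype groups, controls the FDR over
#' all pairs at `coexpr.fdr_q`, and classifies FDR-passing pairs into
#' `co_regulated` / `lnc_only` / `unknown` using the gene's own ASE
#' association with the same SNP.
#'
#' @param associations Association table from [test_associations()].
#' @param regions Region `GRanges` (both lncRNA and protein-coding classes).
#' @param panel SNP panel data.frame.
#' @param phased Phased haplotype list (QC-retained samples).
#' @param cdna_x,cdna_y Raw cDNA intensity matrices.
#' @param config Configuration list.
#' @return data.frame: `region_id`, `gene_id`, `top_snp_id`, `coexpr_p`,
#'   `fdr_pass`, `lnc_ase_p`, `gene_ase_p`, `category` (`NA` category for
#'   pairs failing the FDR).
#' @export
run_coexpression <- function(associations, regions, panel, phased,
                             cdna_x, cdna_y, config = default_config()) {
  lnc <- regions[mcols(regions)$region_class != "protein_coding"]
  genes <- regions[mcols(regions)$region_class == "protein_coding"]
  sig <- associations[associations$significant, , drop = FALSE]
  empty <- data.frame(region_id = character(0), gene_id = character(0),
                      top_snp_id = character(0), coexpr_p = numeric(0),
                      fdr_pass = logical(0), lnc_ase_p = numeric(0),
                      gene_ase_p = numeric(0), category = character(0))
  lnc_ids <- intersect(unique(sig$region_id), mcols(lnc)$region_id)
  if (length(lnc_ids) == 0L || length(genes) == 0L) return(empty)
  near <- nearest_gene(lnc[match(lnc_ids, mcols(lnc)$region_id)], genes)
  samples <- rownames(phased$hap1)
  rows <- lapply(seq_along(lnc_ids), function(i) {
    rid <- lnc_ids[i]
    sub <- sig[sig$region_id == rid, , drop = FALSE]
    top <- sub[which.min(sub$p_value), , drop = FALSE]
    gene_id <- near$gene_id[i]
    if (is.na(gene_id)) return(NULL)
    gene_region <- genes[mcols(genes)$region_id == gene_id]
    gene_snps <- snps_in_region(gene_region, panel)
    expr <- rowMeans(
      cdna_x[samples, gene_snps, drop = FALSE] +
        cdna_y[samples, gene_snps, drop = FALSE],
      na.rm = TRUE
    )
    expr[!is.finite(expr)] <- NA_real_
    dosage <- genotype_dosage(phased$hap1[samples, top$snp_id],
                              phased$hap2[samples, top$snp_id])
    test <- genotype_group_expression_test(dosage, expr)
    # gene evaluable iff it has its own tested ASE window for this SNP
    gene_p <- associations$p_value[associations$region_id == gene_id &
                                     associations$snp_id == top$snp_id]
    gene_within <- near$distance_bp[i] <= config$coexpr.max_gene_distance_bp
    gene_ase_p <- if (length(gene_p) == 1L && gene_within) gene_p else NA_real_
    data.frame(region_id = rid, gene_id = gene_id, top_snp_id = top$snp_id,
               coexpr_p = test$p_value, fdr_pass = NA,
               lnc_ase_p = top$p_value, gene_ase_p = gene_ase_p,
               category = NA_character_)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  testable <- which(!is.na(res$coexpr_p))
  res$fdr_pass <- FALSE
  res$fdr_pass[testable[bh_fdr(res$coexpr_p[testable], config$coexpr.fdr_q)]] <- TRUE
  res$category[res$fdr_pass] <- vapply(
    res$gene_ase_p[res$fdr_pass], classify_pair, "",
    ase_p_thresh = config$coexpr.ase_p_thresh
  )
  res
}
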