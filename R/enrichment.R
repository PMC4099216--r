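#' SNP positions as a GRanges
#' @param panel SNP panel data.frame.
#' @param snp_ids Subset of panel SNP ids (default all).
#' @return A width-1 `GRanges` named by SNP id.
#' @export
snp_granges <- function(panel, snp_ids = panel$snp_id) {
  sub <- panel[match(snp_ids, panel$snp_id), , drop = FALSE]
  if (any(is.na(sub$snp_id))) stop("snp ids absent from panel")
  gr <- GRanges(sub$chrom, IRanges(sub$pos, sub$pos))
  names(gr) <- sub$snp_id
  gr
}

#' Replicate-consensus enhancer peaks
#'
#' Peaks with a calling p-value above `peak_p_thresh` are dropped first.
#' A peak in one replicate is supported by another replicate iff that
#' replicate has a peak of the same mark whose nucleotide overlap with it
#' strictly exceeds `min_overlap` of the shorter peak's length (every peak
#' supports itself). Peaks supported by at least `min_support` replicates
#' are retained and merged per mark, so consensus peaks of a mark never
#' overlap. Invariant under replicate ordering.
#'
#' @param replicate_peaks List of `GRanges`, one per replicate, each with
#'   metadata columns `mark` and `peak_p`.
#' @param min_support Minimum supporting replicates, own included
#'   (default 2).
#' @param min_overlap Overlap fraction of the shorter peak that must be
#'   exceeded (default 0.5, strict).
#' @param peak_p_thresh Maximum peak-calling p-value (default 1e-5).
#' @return A `GRanges` with metadata columns `mark` and `n_support`.
#' @export
consensus_peaks <- function(replicate_peaks, min_support = 2L,
                            min_overlap = 0.5, peak_p_thresh = 1e-5) {
  stopifnot(length(replicate_peaks) >= min_support)
  nm <- names(replicate_peaks)
  if (is.null(nm)) nm <- paste0("rep", seq_along(replicate_peaks))
  for (i in seq_along(replicate_peaks)) {
    if (length(replicate_peaks[[i]]) == 0L) {
      stop(sprintf("replicate '%s' has no peaks", nm[i]))
    }
  }
  all_marks <- unique(unlist(lapply(replicate_peaks, function(g) mcols(g)$mark)))
  per_mark <- lapply(sort(all_marks), function(mk) {
    grl <- lapply(seq_along(replicate_peaks), function(i) {
      g <- replicate_peaks[[i]]
      g <- g[mcols(g)$mark == mk & mcols(g)$peak_p <= peak_p_thresh]
      mcols(g)$replicate <- if (length(g)) i else integer(0)
      g
    })
    pool <- suppressWarnings(do.call(c, grl))
    if (length(pool) == 0L) return(GRanges())
    hits <- findOverlaps(pool, pool)
    qi <- queryHits(hits)
    si <- subjectHits(hits)
    ov <- pmin(end(pool)[qi], end(pool)[si]) - pmax(start(pool)[qi], start(pool)[si]) + 1L
    shorter <- pmin(width(pool)[qi], width(pool)[si])
    good <- ov > min_overlap * shorter
    support <- vapply(seq_along(pool), function(k) {
      length(unique(mcols(pool)$replicate[si[good & qi == k]]))
    }, 0L)
    keep <- pool[support >= min_support]
    if (length(keep) == 0L) return(GRanges())
    merged <- reduce(keep)
    hits2 <- findOverlaps(merged, keep)
    mcols(merged)$mark <- mk
    mcols(merged)$n_support <- vapply(seq_along(merged), function(k) {
      max(support[support >= min_support][subjectHits(hits2)[queryHits(hits2) == k]])
    }, 0L)
    merged
  })
  per_mark <- per_mark[vapply(per_mark, length, 0L) > 0L]
  if (length(per_mark) == 0L) return(GRanges(mark = character(0), n_support = integer(0)))
  suppressWarnings(do.call(c, per_mark))
}

#' Pad intervals with flanking sequence
#'
#' Extends each interval by `pad` bp on both sides, clips at the chromosome
#' origin, and merges intervals that now touch or overlap.
#'
#' @param peaks A `GRanges`.
#' @param pad Flank size in bp (default 2500).
#' @return A merged `GRanges`.
#' @export
flank_peaks <- function(peaks, pad = 2500L) {
  if (length(peaks) == 0L) return(peaks)
  padded <- GRanges(seqnames(peaks),
                    IRanges(pmax(start(peaks) - pad, 1L), end(peaks) + pad))
  reduce(padded)
}

#' Is each SNP position inside an interval set?
#' @param snp_pos Width-1 `GRanges` of SNP positions.
#' @param peaks Interval `GRanges`.
#' @return Logical vector along `snp_pos`.
#' @export
in_peak <- function(snp_pos, peaks) {
  countOverlaps(snp_pos, peaks) > 0L
}

#' Fold enrichment of significant SNPs in peaks
#'
#' Compares the fraction of significantly associated SNPs falling in peaks
#' with the fraction of non-significant SNPs (association p > 0.5) in
#' peaks: `fold = sig in-peak fraction / nonsig in-peak fraction`, with a
#' two-sided Fisher's exact test on the 2x2 in-peak-by-significance table.
#'
#' @param sig_snps,nonsig_snps Width-1 `GRanges` of SNP positions.
#' @param peaks Interval `GRanges`.
#' @return A list with `fold`, `fisher_p`, and the 2x2 `table`
#'   (rows in/out of peaks, columns sig/nonsig).
#' @export
fold_enrichment <- function(sig_snps, nonsig_snps, peaks) {
  if (length(sig_snps) == 0L || length(nonsig_snps) == 0L) {
    stop("both SNP classes must be nonempty")
  }
  sig_in <- sum(in_peak(sig_snps, peaks))
  nonsig_in <- sum(in_peak(nonsig_snps, peaks))
  tab <- matrix(c(sig_in, length(sig_snps) - sig_in,
                  nonsig_in, length(nonsig_snps) - nonsig_in),
                nrow = 2L,
                dimnames = list(c("in_peak", "out_peak"), c("sig", "nonsig")))
  frac_sig <- sig_in / length(sig_snps)
  frac_nonsig <- nonsig_in / length(nonsig_snps)
  fold <- if (frac_nonsig == 0) {
    warning("non-significant in-peak fraction is zero; fold is infinite")
    Inf
  } else {
    frac_sig / frac_nonsig
  }
  list(fold = fold, fisher_p = fisher.test(tab)$p.value, table = tab)
}

#' Enrichment analysis over marks and region classes
#'
#' Builds consensus peaks per mark from the replicate sets and computes the
#' fold enrichment of significant versus non-significant candidate SNPs for
#' each (mark, region class) combination.
#'
#' @param associations Association table from [test_associations()].
#' @param regions Region `GRanges`.
#' @param panel SNP panel data.frame.
#' @param replicate_peaks List of replicate peak `GRanges`.
#' @param config Configuration list.
#' @return A list with the consensus `peaks` (per-mark `GRanges` list) and
#'   `table` (`mark`, `region_set`, counts, `fold`, `fisher_p`).
#' @export
run_enrichment <- function(associations, regions, panel, replicate_peaks,
                           config = default_config()) {
  consensus <- consensus_peaks(replicate_peaks,
                               min_support = config$enrich.min_support,
                               min_overlap = config$enrich.min_overlap,
                               peak_p_thresh = config$enrich.peak_p_thresh)
  class_of <- setNames(mcols(regions)$region_class, mcols(regions)$region_id)
  assoc <- associations
  assoc$region_class <- class_of[assoc$region_id]
  rows <- list()
  peaks_by_mark <- list()
  for (mk in unique(mcols(consensus)$mark)) {
    pk <- consensus[mcols(consensus)$mark == mk]
    peaks_by_mark[[mk]] <- pk
    for (cls in c("intergenic", "protein_coding")) {
      sub <- assoc[assoc$region_class == cls, , drop = FALSE]
      sig_ids <- unique(sub$snp_id[sub$significant])
      nonsig_ids <- setdiff(unique(sub$snp_id[!is.na(sub$p_value) & sub$p_value > 0.5]),
                            sig_ids)
      if (length(sig_ids) == 0L || length(nonsig_ids) == 0L) next
      fe <- fold_enrichment(snp_granges(panel, sig_ids),
                            snp_granges(panel, nonsig_ids), pk)
      rows[[paste(mk, cls)]] <- data.frame(
        mark = mk, region_set = cls,
        n_sig_in = fe$table[1, 1], n_sig_out = fe$table[2, 1],
        n_nonsig_in = fe$table[1, 2], n_nonsig_out = fe$table[2, 2],
        fold = fe$fold, fisher_p = fe$fisher_p
      )
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mark = character(0), region_set = character(0),
               n_sig_in = integer(0), n_sig_out = integer(0),
               n_nonsig_in = integer(0), n_nonsig_out = integer(0),
               fold = numeric(0), fisher_p = numeric(0))
  rownames(tab) <- NULL
  list(peaks = peaks_by_mark, table = tab)
}
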