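peak_gr <- function(chrom, start1, end1, mark = "H3K27ac", p = 1e-8) {
  gr <- GRanges(chrom, IRanges(start1, end1))
  mcols(gr)$mark <- rep(mark, length(gr))
  mcols(gr)$peak_p <- rep(p, length(gr))
  gr
}

test_that("consensus requires support from 2 of 4 replicates", {
  same <- peak_gr("chr1", 1001, 2000)
  other <- peak_gr("chr1", 50001, 51000)
  reps <- list(same, same, other, other)
  cons <- consensus_peaks(reps, min_support = 2L)
  expect_equal(length(cons), 2)
  solo <- list(peak_gr("chr1", 1001, 2000), other, other, other)
  cons2 <- consensus_peaks(solo, min_support = 2L)
  expect_equal(start(cons2), 50001)   # singleton dropped
})

test_that("exactly 50% overlap does not count as support", {
  a <- peak_gr("chr1", 1001, 2000)          # 1000 bp
  b <- peak_gr("chr1", 1501, 2500)          # overlap exactly 500 bp
  filler <- peak_gr("chr2", 1, 100)
  cons <- consensus_peaks(list(a, b, filler, filler), min_support = 2L)
  expect_false(any(seqnames(cons) == "chr1"))
  b2 <- peak_gr("chr1", 1500, 2499)         # overlap 501 bp > 50%
  cons2 <- consensus_peaks(list(a, b2, filler, filler), min_support = 2L)
  expect_true(any(seqnames(cons2) == "chr1"))
})

test_that("weak peaks are dropped before consensus and order does not matter", {
  strong <- peak_gr("chr1", 1001, 2000)
  weak <- peak_gr("chr1", 1001, 2000, p = 1e-3)   # above the 1e-5 cutoff
  filler <- peak_gr("chr2", 1, 100)
  cons <- consensus_peaks(list(strong, weak, filler, filler))
  expect_false(any(seqnames(cons) == "chr1"))
  reps <- list(peak_gr("chr1", 1001, 2000), peak_gr("chr1", 1101, 2100),
               peak_gr("chr3", 5001, 6000), peak_gr("chr1", 901, 1900))
  for (perm in list(1:4, 4:1, c(2, 4, 1, 3))) {
    expect_identical(granges(consensus_peaks(reps)),
                     granges(consensus_peaks(reps[perm])))
  }
  expect_error(consensus_peaks(list(strong, GRanges(), filler, filler)),
               "no peaks")
})

test_that("raising min_support never yields more consensus peaks", {
  set.seed(14)
  reps <- lapply(1:4, function(i) {
    st <- sort(sample(seq(1, 1e6, by = 1500), 80))
    peak_gr("chr1", st, st + 999)
  })
  n_peaks <- vapply(2:4, function(ms) {
    length(consensus_peaks(reps, min_support = ms))
  }, 0L)
  expect_true(all(diff(n_peaks) <= 0))
})

test_that("flanking pads, clips at the origin, and merges", {
  pk <- peak_gr("chr1", 1001, 2000)   # BED [1000, 2000)
  fl <- flank_peaks(pk, 2500L)
  expect_equal(start(fl), 1)          # BED [0, 4500)
  expect_equal(end(fl), 4500)
  two <- peak_gr("chr1", c(1001, 6001), c(2000, 7000))  # 4000 bp apart
  expect_equal(length(flank_peaks(two, 2500L)), 1)
  expect_equal(length(flank_peaks(GRanges(), 2500L)), 0)
})

test_that("fold enrichment and Fisher p match a hypergeometric oracle", {
  # 100 significant SNPs (10 in peaks), 400 non-significant (20 in peaks)
  peaks <- peak_gr("chr1", 1, 1000000)
  sig <- GRanges("chr1", IRanges(c(seq(100, 1000, 100), seq(2e6, 2e6 + 89 * 10, 10)),
                                 width = 1))
  nonsig <- GRanges("chr1", IRanges(c(seq(5000, 24000, 1000), seq(3e6, 3e6 + 379 * 10, 10)),
                                    width = 1))
  fe <- fold_enrichment(sig, nonsig, peaks)
  expect_equal(unname(fe$table[1, ]), c(10, 20))
  expect_equal(fe$fold, 2.0)
  expect_equal(fe$fisher_p, fisher_oracle(fe$table), tolerance = 1e-10)
  fe_same <- fold_enrichment(sig, sig, peaks)
  expect_equal(fe_same$fold, 1.0)
  expect_equal(fe_same$fisher_p, 1.0)
})

test_that("two-sided Fisher equals brute-force enumeration on small tables", {
  set.seed(15)
  for (i in 1:200) {
    n <- sample(10:200, 1)
    tab <- matrix(as.vector(rmultinom(1, n, runif(4, 0.05, 1))), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher.test(tab)$p.value, fisher_oracle(tab), tolerance = 1e-10)
  }
})

test_that("randomly placed peaks give no systematic enrichment", {
  set.seed(16)
  folds <- vapply(1:100, function(i) {
    pos <- sample.int(1e7, 3000)
    snps <- GRanges("chr1", IRanges(pos, width = 1))
    is_sig <- seq_along(pos) <= 600
    st <- sample.int(1e7, 300)
    peaks <- GRanges("chr1", IRanges(st, st + 999))
    fold_enrichment(snps[is_sig], snps[!is_sig], peaks)$fold
  }, 0)
  expect_gte(median(folds), 0.8)
  expect_lte(median(folds), 1.25)
})

test_that("simulated peaks enrich true cis-rSNP positions at the configured odds", {
  cfg <- simulation_config(seed = 17L, peak_enrichment_odds = 3,
                           n_bg_peaks_per_mark = 1000L)
  set.seed(17)
  n_snps <- 5000L
  panel <- data.frame(
    snp_id = sprintf("s%04d", 1:n_snps),
    chrom = rep(sprintf("chr%d", 1:4), each = n_snps / 4),
    pos = rep(seq(1e6, by = 2000, length.out = n_snps / 4), 4),
    allele_a = "A", allele_b = "B"
  )
  true_ids <- panel$snp_id[seq_len(2000)]
  reps <- simulate_peaks(panel, true_ids, cfg)
  cons <- consensus_peaks(reps)
  pk <- cons[mcols(cons)$mark == "H3K4me1"]
  fe <- fold_enrichment(snp_granges(panel, true_ids),
                        snp_granges(panel, setdiff(panel$snp_id, true_ids)), pk)
  expect_gt(fe$fold, 1.5)
  expect_lt(fe$fisher_p, 0.01)
})
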