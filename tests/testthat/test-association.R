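test_that("candidate window is 250 kb on each side, boundaries inclusive", {
  region <- GRanges("chr1", IRanges(1000001, 1020000))
  panel <- data.frame(
    snp_id = c("at_bound", "beyond", "inside", "right_bound", "other_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    pos = c(750001L, 750000L, 1010000L, 1270000L, 1010000L),
    allele_a = "A", allele_b = "B"
  )
  cands <- candidate_snps(region, panel, window_bp = 250000L)
  expect_setequal(cands, c("at_bound", "inside", "right_bound"))
})

test_that("phased genotypes code hom 0, AB +1, BA -1, missing NA", {
  expect_identical(genotype_code(c(0L, 1L, 0L, 1L, NA),
                                 c(0L, 1L, 1L, 0L, 1L)),
                   c(0L, 0L, 1L, -1L, NA))
})

test_that("ASE regression matches the closed-form OLS oracle", {
  codes <- c(-1, -1, 0, 0, 1, 1)
  ase <- c(-0.1, -0.2, 0.0, 0.05, 0.15, 0.2)
  r <- ase_regression(codes, ase)
  expect_equal(r$slope, 0.1625)   # sum(xy)/sum(x^2) = 0.65 / 4
  expect_equal(r$n_ab, 2)
  expect_equal(r$n_ba, 2)
  expect_equal(r$n_hom, 2)
  orc <- ols_oracle(codes, ase)
  expect_equal(r$slope, orc$slope, tolerance = 1e-12)
  expect_equal(r$p_value, orc$p, tolerance = 1e-12)
})

test_that("regression conventions for degenerate inputs hold", {
  codes <- rep(c(-1, 0, 1), 8)
  noiseless <- ase_regression(codes, 0.2 * codes)
  expect_equal(noiseless$slope, 0.2)
  expect_equal(noiseless$p_value, .Machine$double.xmin)
  allzero <- ase_regression(codes, rep(0, 24))
  expect_equal(allzero$slope, 0)
  expect_equal(allzero$p_value, 1)
  same <- ase_regression(rep(1, 10), rnorm(10))
  expect_true(is.na(same$slope))   # zero variance in codes: skipped
})

test_that("regression agrees with lm to 12 significant digits on random inputs", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    codes <- draw_null_codes(n, 0.4)
    if (length(unique(codes)) < 2) next
    ase <- rnorm(n, 0, 0.05)
    r <- ase_regression(codes, ase)
    fit <- summary(lm(ase ~ codes))$coefficients
    expect_equal(r$slope, fit["codes", "Estimate"], tolerance = 1e-12)
    expect_equal(r$p_value, fit["codes", "Pr(>|t|)"], tolerance = 1e-12)
  }
})

test_that("negating codes negates the slope; permutation changes nothing", {
  set.seed(78)
  codes <- draw_null_codes(50, 0.3)
  ase <- rnorm(50, 0.02 * codes, 0.05)
  r <- ase_regression(codes, ase)
  r_neg <- ase_regression(-codes, ase)
  expect_equal(r_neg$slope, -r$slope, tolerance = 1e-12)
  expect_equal(r_neg$p_value, r$p_value, tolerance = 1e-12)
  perm <- sample(50)
  r_perm <- ase_regression(codes[perm], ase[perm])
  expect_equal(r_perm$slope, r$slope, tolerance = 1e-12)
  expect_equal(r_perm$p_value, r$p_value, tolerance = 1e-12)
})

test_that("significance needs p < 1e-6, |slope| >= 0.05 and 4 per class", {
  expect_true(significance_filter(1e-7, 0.06, 5, 5, 20))
  expect_false(significance_filter(1e-7, 0.04, 5, 5, 20))   # low effect
  expect_false(significance_filter(1e-7, 0.06, 3, 10, 20))  # thin class
  expect_false(significance_filter(1e-5, 0.06, 5, 5, 20))   # weak p
  expect_true(significance_filter(1e-7, -0.06, 5, 5, 20))   # sign-blind slope
  expect_false(significance_filter(NA, NA, 0, 0, 20))
})

test_that("LD r2 matches the haplotype-correlation definition", {
  expect_equal(ld_r2(c(1, 0, 1, 0, 1), c(1, 0, 1, 0, 1)), 1)
  # pairs (1,1),(1,1),(0,0),(0,1): D = 0.5 - 0.375, r2 = 1/3
  expect_equal(ld_r2(c(1, 1, 0, 0), c(1, 1, 0, 1)), 1 / 3)
  expect_true(is.na(ld_r2(c(1, 1, 1), c(0, 1, 0))))
  set.seed(12)
  a <- rbinom(10000, 1, 0.4)
  b <- rbinom(10000, 1, 0.3)
  expect_lt(ld_r2(a, b), 0.01)
  # squared Pearson correlation is an equivalent formulation
  for (i in 1:20) {
    x <- rbinom(50, 1, 0.5)
    y <- ifelse(runif(50) < 0.7, x, rbinom(50, 1, 0.5))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(ld_r2(x, y), cor(x, y)^2, tolerance = 1e-12)
  }
})

test_that("slope converts to percent expression difference as 400 * slope", {
  expect_equal(slope_to_percent_diff(0.05), 20)
  expect_equal(slope_to_percent_diff(0), 0)
  expect_equal(slope_to_percent_diff(0.25), 100)
  expect_warning(res <- slope_to_percent_diff(0.6), "capped")
  expect_equal(res, 200)
})

test_that("greedy LD pruning keeps one tag per perfectly correlated pair", {
  set.seed(9)
  a <- rbinom(200, 1, 0.4)
  haps <- cbind(s1 = a, s2 = a, s3 = rbinom(200, 1, 0.4))
  kept <- ld_prune(haps, r2_thresh = 0.9)
  expect_true("s1" %in% kept)
  expect_false("s2" %in% kept)
  expect_true("s3" %in% kept)
})

test_that("type-I error of the association test is calibrated at alpha 0.05", {
  set.seed(1001)
  n_tests <- 10000L
  n <- 188L
  hits <- vapply(seq_len(n_tests), function(i) {
    codes <- draw_null_codes(n, 0.3)
    ase <- rnorm(n, 0, 0.03)
    ase_regression(codes, ase)$p_value < 0.05
  }, TRUE)
  rate <- mean(hits)
  half_width <- qnorm(0.995) * sqrt(0.05 * 0.95 / n_tests)
  expect_gt(rate, 0.05 - half_width)
  expect_lt(rate, 0.05 + half_width)
})
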