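test_that("per-SNP ASE is the cDNA minus gDNA oriented fraction", {
  expect_equal(snp_ase(0.75, 0.50), 0.25)
  expect_equal(snp_ase(0.42, 0.42), 0)
  expect_equal(snp_ase(0.50, 0.55), -0.05)
})

test_that("fractions are oriented to the haplotype-1 allele", {
  # hap1 carries allele B: an A-fraction of 0.3 is a hap1-allele fraction of 0.7
  expect_equal(orient_fraction(0.3, 1L), 0.7)
  expect_equal(orient_fraction(0.3, 0L), 0.3)
})

test_that("ASE is only computed at heterozygous gDNA calls", {
  dn <- list(c("S1", "S2"), c("rs1", "rs2"))
  gdna <- matrix(0.5, 2, 2, dimnames = dn)
  cdna <- matrix(c(0.7, 0.9, 0.4, 0.2), 2, 2, dimnames = dn)
  calls <- matrix(c("AB", "AA", "AB", "AB"), 2, 2, dimnames = dn)
  hap1 <- matrix(c(0L, 0L, 1L, NA), 2, 2, dimnames = dn)
  ase <- ase_snp_matrix(gdna, cdna, calls, hap1)
  expect_equal(ase["S1", "rs1"], 0.2)
  expect_true(is.na(ase["S2", "rs1"]))     # homozygous: excluded, not 0
  expect_equal(ase["S1", "rs2"], (1 - 0.4) - 0.5)  # hap1 allele is B
  expect_true(is.na(ase["S2", "rs2"]))     # no phase
})

test_that("window ASE averages het SNPs per sample and needs 3 informative SNPs", {
  dn <- list("S1", c("a", "b", "c"))
  ase <- matrix(c(0.2, 0.3, 0.25), 1, 3, dimnames = dn)
  w <- window_ase(c("a", "b", "c"), ase, min_informative = 3L)
  expect_equal(unname(w$ase["S1"]), 0.25)
  expect_true(w$informative)
  w2 <- window_ase(c("a", "b"), ase, min_informative = 3L)
  expect_false(w2$informative)             # 2 informative SNPs: excluded
  # mean idempotence: identical per-SNP values pass through
  ase3 <- matrix(0.1, 1, 3, dimnames = dn)
  expect_equal(unname(window_ase(c("a", "b", "c"), ase3)$ase["S1"]), 0.1)
})

test_that("relabeling alleles A/B at every SNP negates all ASE levels", {
  set.seed(5)
  dn <- list(sprintf("S%d", 1:10), sprintf("rs%d", 1:4))
  gdna <- matrix(runif(40, 0.4, 0.6), 10, 4, dimnames = dn)
  cdna <- matrix(runif(40, 0.2, 0.8), 10, 4, dimnames = dn)
  calls <- matrix("AB", 10, 4, dimnames = dn)
  hap1 <- matrix(rbinom(40, 1, 0.5), 10, 4, dimnames = dn)
  ase <- ase_snp_matrix(gdna, cdna, calls, hap1)
  # relabeling measures the fractions on allele B instead of allele A while
  # the window stays oriented to the same labels: every ASE level negates
  ase_flip <- ase_snp_matrix(1 - gdna, 1 - cdna, calls, hap1)
  expect_equal(ase_flip, -ase, tolerance = 1e-12)
  w <- window_ase(dn[[2]], ase)
  w_flip <- window_ase(dn[[2]], ase_flip)
  expect_equal(w_flip$ase, -w$ase, tolerance = 1e-12)
  # relabeling fractions *and* allele codes together is a pure gauge change:
  # ASE anchored to physical haplotype 1 is untouched
  ase_gauge <- ase_snp_matrix(1 - gdna, 1 - cdna, calls, 1L - hap1)
  expect_equal(ase_gauge, ase, tolerance = 1e-12)
  # flipping the phase orientation of one sample negates its window ASE only
  hap1_s1 <- hap1
  hap1_s1["S1", ] <- 1L - hap1_s1["S1", ]
  w_s1 <- window_ase(dn[[2]], ase_snp_matrix(gdna, cdna, calls, hap1_s1))
  expect_equal(unname(w_s1$ase["S1"]), -unname(w$ase["S1"]), tolerance = 1e-12)
  expect_equal(w_s1$ase[-1], w$ase[-1], tolerance = 1e-12)
})

test_that("total expression is the mean two-channel cDNA signal sum", {
  dn <- list("S1", "rs1")
  expect_equal(expression_level(matrix(600, 1, 1, dimnames = dn),
                                matrix(500, 1, 1, dimnames = dn), "rs1"), 1100)
  dn2 <- list(c("S1", "S2"), c("rs1", "rs2"))
  x <- matrix(c(300, 600, 700, 400), 2, 2, dimnames = dn2)
  y <- matrix(c(500, 400, 500, 600), 2, 2, dimnames = dn2)
  expect_equal(expression_level(x, y, c("rs1", "rs2")), 1000)
  expect_equal(expression_level(x * 0, y * 0, c("rs1", "rs2")), 0)
})

test_that("the expression threshold of 1000 units is inclusive", {
  expect_true(expression_filter(1000))
  expect_false(expression_filter(999))
  expect_true(expression_filter(3300))
  expect_false(expression_filter(0))
})

test_that("window ASE has mean zero when there is no allelic imbalance", {
  cfg <- simulation_config(n_regions = 30L, cis_effect_fraction = 0,
                           dye_bias_coeffs = c(1, 0.075, 0), seed = 31L)
  b <- simulate_bundle(cfg)
  res <- run_pipeline(b, skip = c("enrichment", "coexpression", "gwas"),
                      quiet = TRUE)
  vals <- res$windows$ase[!is.na(res$windows$ase)]
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})
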