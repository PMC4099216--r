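test_that("identical config and seed reproduce byte-identical bundles", {
  cfg <- simulation_config(n_regions = 8L, seed = 41L)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  write_bundle(simulate_bundle(cfg), d1)
  write_bundle(simulate_bundle(cfg), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 13)
  for (f in files) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     label = sprintf("file %s from the second run", f))
  }
  # and a different seed changes the data
  d3 <- file.path(tempdir(), "bundle_c")
  write_bundle(simulate_bundle(simulation_config(n_regions = 8L, seed = 42L)), d3)
  expect_false(identical(readLines(file.path(d3, "phased.tsv")),
                         readLines(file.path(d1, "phased.tsv"))))
})

test_that("bundles survive a write/read cycle", {
  cfg <- simulation_config(n_regions = 6L, seed = 43L)
  b <- simulate_bundle(cfg)
  d <- file.path(tempdir(), "bundle_rt")
  write_bundle(b, d)
  b2 <- read_bundle(d)
  expect_identical(b2$phased, b$phased)
  expect_identical(b2$genotypes, b$genotypes)
  expect_equal(b2$gdna_x, round(b$gdna_x, 4))
  expect_identical(mcols(b2$regions)$region_id, mcols(b$regions)$region_id)
  expect_identical(b2$catalog, b$catalog)
  expect_equal(length(b2$peaks), 4)
})

test_that("haplotype LD follows the block correlation parameter", {
  set.seed(44)
  h0 <- simulate_haplotypes(runif(8, 0.2, 0.5), 10000L, rho = 0)
  r2s <- combn(8, 2, function(jk) ld_r2(h0[, jk[1]], h0[, jk[2]]))
  expect_lt(max(r2s), 0.01)
  h1 <- simulate_haplotypes(rep(0.3, 5), 2000L, rho = 1)
  r2s1 <- combn(5, 2, function(jk) ld_r2(h1[, jk[1]], h1[, jk[2]]))
  expect_equal(as.vector(r2s1), rep(1, 10))
  h_mid <- simulate_haplotypes(rep(0.3, 2), 20000L, rho = 0.9)
  expect_gt(ld_r2(h_mid[, 1], h_mid[, 2]), 0.4)
})

test_that("simulated genotypes respect Hardy-Weinberg proportions", {
  set.seed(45)
  n_snps <- 10000L
  n <- 188L
  h <- simulate_haplotypes(runif(n_snps, 0.1, 0.5), 2L * n, rho = 0)
  dosage <- h[2 * (1:n) - 1, ] + h[2 * (1:n), ]
  p <- vapply(seq_len(n_snps), function(j) {
    hwe_chisq(sum(dosage[, j] == 0), sum(dosage[, j] == 1),
              sum(dosage[, j] == 2))$p
  }, 0)
  expect_gte(mean(p > 1e-6), 0.999)
})

test_that("noise-free effect construction gives het cDNA fractions of 0.6", {
  cfg <- simulation_config(n_regions = 4L, cis_effect_fraction = 1,
                           noise_sd = 0, dye_bias_coeffs = c(1, 0, 0),
                           maf_range = c(0.5, 0.5), ld_block_rho = 1,
                           frac_hwe_bad_snps = 0, seed = 46L)
  b <- simulate_bundle(cfg)
  tr <- b$truth
  for (r in seq_len(nrow(tr))) {
    rsnp <- tr$true_cis_rsnp_id[r]
    region <- b$regions[mcols(b$regions)$region_id == tr$region_id[r]]
    ids <- snps_in_region(region, b$panel)
    h1 <- b$phased$hap1
    h2 <- b$phased$hap2
    het_r <- h1[, rsnp] != h2[, rsnp]
    frac <- b$cdna_x[, ids] / (b$cdna_x[, ids] + b$cdna_y[, ids])
    for (s in rownames(h1)) {
      for (snp in ids) {
        f_obs <- frac[s, snp]
        if (h1[s, snp] == h2[s, snp]) {
          # homozygous SNP: fraction 0 or 1 regardless of the effect
          expect_equal(f_obs, ifelse(h1[s, snp] == 0L, 1, 0))
        } else if (het_r[s]) {
          f_hap1 <- ifelse(h1[s, snp] == 0L, f_obs, 1 - f_obs)
          expected <- ifelse(h1[s, rsnp] == 1L, 0.6, 0.4)
          expect_equal(f_hap1, expected, tolerance = 1e-12)
        } else {
          expect_equal(f_obs, 0.5)
        }
      }
    }
  }
})

test_that("channel signals are nonnegative and sum to the drawn totals", {
  b <- simulate_bundle(simulation_config(n_regions = 6L, seed = 47L,
                                         dye_bias_coeffs = c(1, 0, 0)))
  for (nm in c("gdna_x", "gdna_y", "cdna_x", "cdna_y")) {
    expect_true(all(b[[nm]] >= 0))
  }
  # without dye bias the x+y sums are exactly the drawn lognormal totals
  totals <- b$gdna_x + b$gdna_y
  expect_true(all(totals > 0))
  expect_lt(abs(mean(log(totals)) - log(5000)), 0.05)
})
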