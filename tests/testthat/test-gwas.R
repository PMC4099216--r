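make_assoc <- function(region_id, snp_id) {
  data.frame(region_id = region_id, snp_id = snp_id, distance_bp = 0L,
             slope = 0.1, p_value = 1e-8, n_ab = 10L, n_ba = 10L,
             n_hom = 50L, significant = TRUE)
}

test_that("direct and proxy catalog overlaps are detected at the r2 threshold", {
  set.seed(31)
  n <- 400
  a <- rbinom(n, 1, 0.4)
  proxy_strong <- ifelse(runif(n) < 0.97, a, rbinom(n, 1, 0.4))  # r2 ~ 0.9
  weak <- ifelse(runif(n) < 0.6, a, rbinom(n, 1, 0.4))           # r2 ~ 0.4
  haps <- cbind(rs_cis = a, rs_strong = proxy_strong, rs_weak = weak)
  stopifnot(ld_r2(a, proxy_strong) >= 0.8, ld_r2(a, weak) < 0.8)
  assoc <- make_assoc("L1", "rs_cis")
  catalog <- data.frame(
    snp_id = c("rs_cis", "rs_strong", "rs_weak"),
    trait = c("trait A", "trait B", "trait C"),
    immune_related = c(TRUE, FALSE, FALSE)
  )
  ov <- overlap_catalog(assoc, catalog, haps, r2_thresh = 0.8)
  expect_setequal(ov$catalog_snp_id, c("rs_cis", "rs_strong"))
  expect_equal(ov$ld_r2[ov$catalog_snp_id == "rs_cis"], 1.0)
  direct <- ov[ov$ld_r2 == 1, ]
  expect_equal(direct$cis_rsnp_id, direct$catalog_snp_id)
  # catalog SNP absent from the haplotype panel is skipped, not an error
  catalog2 <- rbind(catalog, data.frame(snp_id = "rs_unseen", trait = "t",
                                        immune_related = FALSE))
  ov2 <- overlap_catalog(assoc, catalog2, haps, r2_thresh = 0.8)
  expect_false("rs_unseen" %in% ov2$catalog_snp_id)
})

test_that("overlaps are monotone in the LD threshold and contain direct hits", {
  set.seed(32)
  n <- 400
  a <- rbinom(n, 1, 0.4)
  haps <- cbind(rs_cis = a,
                p1 = ifelse(runif(n) < 0.95, a, rbinom(n, 1, 0.4)),
                p2 = ifelse(runif(n) < 0.8, a, rbinom(n, 1, 0.4)),
                p3 = ifelse(runif(n) < 0.6, a, rbinom(n, 1, 0.4)))
  assoc <- make_assoc("L1", "rs_cis")
  catalog <- data.frame(snp_id = colnames(haps),
                        trait = paste("t", 1:4),
                        immune_related = FALSE)
  prev <- character(0)
  for (thr in c(0.95, 0.8, 0.5, 0.2)) {
    cur <- overlap_catalog(assoc, catalog, haps, r2_thresh = thr)$catalog_snp_id
    expect_true(all(prev %in% cur))   # lowering the threshold only adds
    expect_true("rs_cis" %in% cur)    # direct hits at any threshold
    prev <- cur
  }
})

test_that("immune over-representation matches the hypergeometric oracle", {
  catalog <- data.frame(
    snp_id = sprintf("rs%04d", 1:1000),
    trait = sprintf("trait%04d", 1:1000),
    immune_related = rep(c(TRUE, FALSE), each = 500)
  )
  overlaps <- data.frame(catalog_snp_id = sprintf("rs%04d", 1:10))  # all immune
  te <- trait_enrichment(overlaps, catalog)
  expect_equal(te$fisher_p, fisher_oracle(matrix(c(10, 0, 490, 500), 2)),
               tolerance = 1e-10)
  none <- trait_enrichment(overlaps[0, , drop = FALSE], catalog)
  expect_equal(none$fisher_p, 1)
  all_imm <- catalog
  all_imm$immune_related <- TRUE
  expect_true(is.na(trait_enrichment(overlaps, all_imm)$fisher_p))
})

test_that("uniformly drawn overlaps give a calibrated immune test", {
  set.seed(33)
  catalog <- data.frame(
    snp_id = sprintf("rs%04d", 1:1000),
    trait = sprintf("trait%04d", 1:1000),
    immune_related = rep(c(TRUE, FALSE), c(300, 700))
  )
  pvals <- vapply(1:200, function(i) {
    overlaps <- data.frame(catalog_snp_id = sample(catalog$snp_id, 30))
    trait_enrichment(overlaps, catalog)$fisher_p
  }, 0)
  # null rejection rate near (and, the exact test being conservative, at or
  # below) the nominal 5%
  expect_lte(mean(pvals < 0.05), 0.09)
  expect_gt(mean(pvals < 0.5), 0.25)
})

test_that("enhancer context annotation agrees with the in-peak predicate", {
  panel <- data.frame(
    snp_id = c("in_k4", "in_k27", "in_flank", "outside"),
    chrom = "chr1",
    pos = c(1500L, 11500L, 21800L, 500000L),
    allele_a = "A", allele_b = "B"
  )
  k4 <- GRanges("chr1", IRanges(1001, 2000))
  k27 <- GRanges("chr1", IRanges(11001, 12000))
  flank_src <- GRanges("chr1", IRanges(20001, 21000))
  peaks <- list(H3K4me1 = k4, H3K27ac = c(k27, flank_src))
  ov <- data.frame(region_id = "L1", cis_rsnp_id = panel$snp_id,
                   catalog_snp_id = panel$snp_id, ld_r2 = 1,
                   trait = "t", immune_related = FALSE)
  ann <- annotate_enhancer_context(ov, panel, peaks, flank_bp = 2500L)
  expect_equal(ann$in_peak, c("in_H3K4me1", "in_H3K27ac", "flank_2.5kb", "none"))
  pos <- snp_granges(panel)
  expect_equal(unname(in_peak(pos, k4)), c(TRUE, FALSE, FALSE, FALSE))
})
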