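suppressPackageStartupMessages(library(GenomicRanges))

# Independent oracles used to check the package's statistics. These are
# deliberately naive implementations (enumeration / closed forms) and never
# call the functions they verify.

# Closed-form OLS slope and two-sided t-test p-value.
ols_oracle <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  fit <- yb + slope * (x - xb)
  rss <- sum((y - fit)^2)
  n <- length(x)
  se <- sqrt(rss / (n - 2) / sum((x - xb)^2))
  t <- slope / se
  list(slope = slope, p = 2 * pt(abs(t), df = n - 2, lower.tail = FALSE))
}

# Two-sided Fisher exact p by enumeration over all tables with fixed margins:
# sum of hypergeometric probabilities not exceeding the observed table's.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[, 1])   # first-column margin
  n <- sum(tab[, 2])
  k <- sum(tab[1, ])   # first-row margin
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by direct definition.
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0) return(integer(0))
  sort(ord[seq_len(max(ok))])
}

# Genotype codes for a null association draw: phased HWE genotypes at a
# given MAF, coded hom = 0, AB = +1, BA = -1.
draw_null_codes <- function(n, maf) {
  h1 <- rbinom(n, 1, maf)
  h2 <- rbinom(n, 1, maf)
  ifelse(h1 == h2, 0L, ifelse(h1 == 1L, -1L, 1L))
}
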