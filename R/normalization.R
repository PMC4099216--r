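#' Per-bin medians on a log10 grid
#'
#' Splits `values` into `n_bins` equal-count bins ordered by
#' `log10(binning_values)` and returns, per bin, the median of the binning
#' variable and the median of `values`. Non-positive binning values are
#' excluded (they have no log) and their count reported.
#'
#' @param values Numeric vector to summarize per bin.
#' @param binning_values Numeric vector defining bin membership (defaults to
#'   `values` itself).
#' @param n_bins Number of equal-count bins (>= 3).
#' @return A `data.frame` with `bin`, `log10_center` (log10 of the bin median
#'   of the binning variable), `bin_median` (median of `values` in the bin)
#'   and `n`.
#' @export
binned_medians <- function(values, binning_values = values, n_bins = 100L) {
  stopifnot(length(values) == length(binning_values), n_bins >= 3L)
  keep <- !is.na(values) & !is.na(binning_values) & binning_values > 0
  n_dropped <- sum(!keep & !is.na(binning_values))
  if (n_dropped > 0L) {
    message(sprintf("binned_medians: excluded %d non-positive signals", n_dropped))
  }
  v <- values[keep]
  b <- binning_values[keep]
  if (length(v) < n_bins) {
    stop(sprintf("need at least %d positive signals, got %d", n_bins, length(v)))
  }
  ord <- order(log10(b), b)
  # equal-count bins by rank; ties in log10 resolved by raw value then order
  idx <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  idx[idx > n_bins] <- n_bins
  bin_of <- integer(length(v))
  bin_of[ord] <- idx
  data.frame(
    bin = seq_len(n_bins),
    log10_center = log10(vapply(seq_len(n_bins), function(j) median(b[bin_of == j]), 0)),
    bin_median = vapply(seq_len(n_bins), function(j) median(v[bin_of == j]), 0),
    n = tabulate(bin_of, n_bins)
  )
}

#' Fit a quadratic intensity-normalization model for one channel
#'
#' The model removes the dependency of allele fractions on fluorophore
#' intensity. Observations (pooled over samples, one template at a time) are
#' binned into equal-count bins on log10 of the binning signal -- by default
#' the channel's own signal; in the pipeline the total (x + y) signal of
#' heterozygous calls, where the channel's expected share is half the total,
#' so the bin medians trace the channel's intensity-dependent response.
#' The intensity prediction works on the log10 scale throughout: a quadratic
#' `q(L) = a + b*L + c*L^2` in `L = log10(signal)` is least-squares fitted to
#' the (log10 bin-median of the binning signal, log10 bin-median of the
#' channel) pairs and the predicted intensity is `10^q(L)`. Working in log10
#' keeps the prediction strictly positive and makes the adjustment an exact
#' no-op when both channels are unbiased (both fits then see the same data
#' shape and cancel in the fraction).
#'
#' @param raw_signals Channel signal per observation.
#' @param binning_signals Signal whose log10 defines the bins (default: the
#'   channel signal itself).
#' @param n_bins Number of equal-count bins (config `norm.n_bins`).
#' @param channel Channel label, `"x"` or `"y"`.
#' @return An object of class `normalization_model` with elements `channel`,
#'   `bin_edges` (log10 bin centers), `bin_medians` (channel bin medians on
#'   the intensity scale), `coeffs` (a, b, c of the quadratic in log10
#'   intensity) and `floor` (1st percentile of the raw signal, below which
#'   predictions are clamped).
#' @export
fit_normalization <- function(raw_signals, binning_signals = raw_signals,
                              n_bins = 100L, channel = "x") {
  bm <- binned_medians(raw_signals, binning_signals, n_bins)
  if (length(unique(bm$bin_median)) == 1L && length(unique(bm$log10_center)) == 1L) {
    stop("all signals equal: quadratic fit is singular")
  }
  if (any(bm$bin_median <= 0)) {
    stop("non-positive channel bin median: cannot fit on the log10 scale")
  }
  L <- bm$log10_center
  fit <- lm(lm10 ~ L + I(L^2),
            data = data.frame(lm10 = log10(bm$bin_median), L = L))
  coeffs <- unname(coef(fit))
  coeffs[is.na(coeffs)] <- 0
  flr <- as.numeric(quantile(raw_signals[!is.na(raw_signals) & raw_signals > 0],
                             0.01, names = FALSE))
  structure(
    list(channel = match.arg(channel, c("x", "y")),
         bin_edges = bm$log10_center,
         bin_medians = bm$bin_median,
         coeffs = coeffs,
         floor = flr,
         fitted_range = range(L)),
    class = "normalization_model"
  )
}

#' Predict the typical channel intensity at a given signal level
#' @param model A `normalization_model`.
#' @param signal Raw signal at which to evaluate (its log10 is taken).
#' @return Predicted intensity, floored at the model's 1st-percentile floor.
#' @export
predict_intensity <- function(model, signal) {
  L <- log10(signal)
  p <- 10^(model$coeffs[1] + model$coeffs[2] * L + model$coeffs[3] * L^2)
  pmax(p, model$floor)
}

#' Constant (identity) normalization model
#'
#' A model whose prediction is the same for every signal level; adjusting
#' with equal constant models for both channels returns the raw fraction
#' unchanged. Used for diagnostics and as the no-bias reference.
#'
#' @param value The constant predicted intensity (> 0).
#' @param channel Channel label.
#' @return A `normalization_model`.
#' @export
constant_model <- function(value = 1, channel = "x") {
  stopifnot(value > 0)
  structure(
    list(channel = match.arg(channel, c("x", "y")),
         bin_edges = numeric(0), bin_medians = numeric(0),
         coeffs = c(log10(value), 0, 0), floor = value,
         fitted_range = c(-Inf, Inf)),
    class = "normalization_model"
  )
}

#' Adjusted allele fraction
#'
#' Divides each channel's raw signal by its model-predicted typical
#' intensity at the observation's total signal and renormalizes:
#' `f = (x/px) / (x/px + y/py)`, clipped to `[0, 1]`. A zero total signal
#' yields `NA` (missing), never 0.5. Vectorized over observations.
#'
#' @param x_raw,y_raw Raw intensities of the two channels (allele A = x,
#'   allele B = y).
#' @param model_x,model_y Fitted `normalization_model`s for the two channels.
#' @return Adjusted allele-A fraction in `[0, 1]`, `NA` where undefined.
#' @export
adjust_fraction <- function(x_raw, y_raw, model_x, model_y) {
  stopifnot(length(x_raw) == length(y_raw))
  total <- x_raw + y_raw
  out <- rep(NA_real_, length(x_raw))
  ok <- !is.na(total) & total > 0
  px <- predict_intensity(model_x, total[ok])
  py <- predict_intensity(model_y, total[ok])
  xs <- x_raw[ok] / px
  ys <- y_raw[ok] / py
  out[ok] <- pmin(pmax(xs / (xs + ys), 0), 1)
  out
}

#' Fit both channel models for one template
#'
#' Fits the x and y channel models on heterozygous calls only (where the two
#' alleles are present 1:1 in gDNA, so any systematic departure of a
#' channel's bin median from half the total is dye bias), binning on the
#' total signal. Models are fitted separately per template (gDNA or cDNA)
#' but pooled over samples.
#'
#' @param x,y Sample-by-SNP raw intensity matrices for the template.
#' @param het_mask Logical matrix: TRUE where the gDNA call is heterozygous.
#' @param n_bins Number of bins.
#' @return A list with `normalization_model`s `x` and `y`.
#' @export
fit_template_models <- function(x, y, het_mask, n_bins = 100L) {
  stopifnot(all(dim(x) == dim(y)), all(dim(x) == dim(het_mask)))
  sel <- het_mask & !is.na(x) & !is.na(y)
  xv <- x[sel]
  yv <- y[sel]
  total <- xv + yv
  list(
    x = fit_normalization(xv, total, n_bins = n_bins, channel = "x"),
    y = fit_normalization(yv, total, n_bins = n_bins, channel = "y")
  )
}

#' Adjusted allele fractions for a whole template
#' @param x,y Sample-by-SNP raw intensity matrices.
#' @param models List with channel models `x` and `y`
#'   (from [fit_template_models()]).
#' @return Matrix of adjusted allele-A fractions (same dimnames).
#' @export
adjust_fraction_matrix <- function(x, y, models) {
  f <- adjust_fraction(as.vector(x), as.vector(y), models$x, models$y)
  matrix(f, nrow(x), ncol(x), dimnames = dimnames(x))
}

#' Serialize a normalization model to TSV
#' @param model A `normalization_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normalization_model <- function(model, path) {
  hdr <- data.table(
    field = c("channel", "coeff_a", "coeff_b", "coeff_c", "floor"),
    value = c(model$channel, format(model$coeffs, digits = 17),
              format(model$floor, digits = 17))
  )
  bins <- data.table(
    field = rep("bin", length(model$bin_edges)),
    value = paste(format(model$bin_edges, digits = 17),
                  format(model$bin_medians, digits = 17), sep = ",")
  )
  fwrite(rbind(hdr, bins), path, sep = "\t")
  invisible(path)
}

#' Read a serialized normalization model
#' @param path Path written by [write_normalization_model()].
#' @return A `normalization_model`.
#' @export
read_normalization_model <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  get1 <- function(k) dt$value[dt$field == k]
  bins <- do.call(rbind, strsplit(dt$value[dt$field == "bin"], ",", fixed = TRUE))
  edges <- if (is.null(bins)) numeric(0) else as.numeric(bins[, 1])
  meds <- if (is.null(bins)) numeric(0) else as.numeric(bins[, 2])
  structure(
    list(channel = get1("channel"),
         bin_edges = edges, bin_medians = meds,
         coeffs = as.numeric(c(get1("coeff_a"), get1("coeff_b"), get1("coeff_c"))),
         floor = as.numeric(get1("floor")),
         fitted_range = range(edges)),
    class = "normalization_model"
  )
}
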