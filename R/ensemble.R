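#' Summarize n generated volumes into an ensemble
#'
#' Computes the pixel-wise mean `(1/n) sum y_i`, the population-style
#' standard deviation `sqrt((1/n) sum (y_i - mean)^2)` (1/n, not 1/(n-1),
#' matching the ensemble formulas the uncertainty maps are defined with) and
#' the pixel-wise median.
#'
#' @param samples list of n (S, H, W) arrays or [volume()]s of equal shape.
#' @param model_tag label of the generating model.
#' @param input_ref subject/contrast reference of the input.
#' @return an `mrt_ensemble`: `samples` (S, H, W, n array), `mean`, `std`,
#'   `median`, `n`, `model_tag`, `input_ref`.
#' @export
ens_summarize <- function(samples, model_tag = "", input_ref = "") {
  stop_if_not(length(samples) >= 1, "need at least one sample")
  arrs <- lapply(samples, function(s) if (inherits(s, "volume")) s$data else s)
  d <- dim(arrs[[1]])
  for (a in arrs) stop_if_not(all(dim(a) == d), "sample shapes differ")
  n <- length(arrs)
  flat <- matrix(0, prod(d), n)
  for (i in seq_len(n)) flat[, i] <- arrs[[i]]
  mu <- rowMeans(flat)
  std <- sqrt(rowMeans((flat - mu)^2))
  med <- apply(flat, 1L, stats::median)
  samp <- array(flat, c(d, n))
  structure(list(samples = samp, mean = array(mu, d), std = array(std, d),
                 median = array(med, d), n = n, model_tag = model_tag,
                 input_ref = input_ref),
            class = "mrt_ensemble")
}

#' Scalar uncertainty score: mean in-mask standard deviation
#'
#' The OOD score: the pixel-wise standard deviation averaged over all brain
#' voxels of the volume.
#'
#' @param ens an `mrt_ensemble`.
#' @param mask logical array matching the volume shape; must be nonempty.
#' @return scalar score (>= 0).
#' @export
sigma_hat <- function(ens, mask) {
  stop_if_not(inherits(ens, "mrt_ensemble"), "ens must be an mrt_ensemble")
  stop_if_not(all(dim(mask) == dim(ens$std)), "mask shape mismatch")
  if (!any(mask)) stop("empty mask", call. = FALSE)
  mean(ens$std[as.logical(mask)])
}

#' Regression-calibration (coverage) curve
#'
#' For each confidence level c, builds the central interval
#' [q((1-c)/2), q((1+c)/2)] of each pixel's sample distribution (empirical
#' quantiles, linear interpolation) and reports the fraction of masked pixels
#' whose true target value falls inside, averaged over subjects. A
#' well-calibrated generator tracks the diagonal; curves above it are
#' underconfident (intervals too wide), below it overconfident.
#'
#' @param ensembles list of `mrt_ensemble`s (n >= 2 each).
#' @param targets list of matching target [volume()]s or arrays.
#' @param levels confidence levels in (0, 1).
#' @param masks optional list of logical arrays.
#' @return a `coverage_curve` data frame with `level` and `coverage`.
#' @export
coverage_curve <- function(ensembles, targets, levels = seq(0.05, 0.95, by = 0.05),
                           masks = NULL) {
  stop_if_not(length(ensembles) == length(targets), "one target per ensemble")
  if (any(levels <= 0 | levels >= 1)) {
    stop("confidence levels must lie strictly inside (0, 1)", call. = FALSE)
  }
  cov_mat <- matrix(0, length(ensembles), length(levels))
  for (i in seq_along(ensembles)) {
    ens <- ensembles[[i]]
    stop_if_not(ens$n >= 2, "coverage needs n >= 2 samples per ensemble")
    tg <- targets[[i]]
    tga <- if (inherits(tg, "volume")) tg$data else tg
    d <- dim(ens$mean)
    msk <- if (is.null(masks)) array(TRUE, d) else as.logical(masks[[i]])
    flat <- ens$samples
    dim(flat) <- c(prod(d), ens$n)
    flat <- flat[msk, , drop = FALSE]
    tv <- tga[msk]
    probs <- sort(unique(c((1 - levels) / 2, (1 + levels) / 2)))
    qs <- t(apply(flat, 1L, stats::quantile, probs = probs, names = FALSE))
    for (j in seq_along(levels)) {
      lo <- qs[, match((1 - levels[j]) / 2, probs)]
      hi <- qs[, match((1 + levels[j]) / 2, probs)]
      cov_mat[i, j] <- mean(tv >= lo & tv <= hi)
    }
  }
  structure(data.frame(level = levels, coverage = colMeans(cov_mat)),
            class = c("coverage_curve", "data.frame"))
}

#' Per-pixel distributional report for an ensemble
#'
#' On a random subsample of masked pixels, tests normality of the n sample
#' values (Shapiro-Wilk) and computes the first four cumulants: mean,
#' variance, third central moment, and fourth central moment minus
#' `3 sigma^4` (excess-kurtosis numerator). Cumulants use population (1/n)
#' moments.
#'
#' @param ens an `mrt_ensemble` with n >= 8.
#' @param mask optional logical array.
#' @param alpha significance level for the normality test.
#' @param n_pixels number of pixels sampled.
#' @param seed subsampling seed.
#' @return list with a per-pixel data frame (`shapiro_p`, `reject`,
#'   `k1`..`k4`) and `fraction_normal`, the fraction of pixels failing to
#'   reject normality.
#' @export
pixel_distribution_report <- function(ens, mask = NULL, alpha = 0.05,
                                      n_pixels = 2000L, seed = 1L) {
  stop_if_not(inherits(ens, "mrt_ensemble"), "ens must be an mrt_ensemble")
  if (ens$n < 8L) stop("distribution report needs n >= 8 samples", call. = FALSE)
  d <- dim(ens$mean)
  msk <- if (is.null(mask)) array(TRUE, d) else as.logical(mask)
  idx <- which(msk)
  if (length(idx) > n_pixels) idx <- with_seed(seed, sample(idx, n_pixels))
  flat <- ens$samples
  dim(flat) <- c(prod(d), ens$n)
  vals <- flat[idx, , drop = FALSE]
  k1 <- rowMeans(vals)
  cent <- vals - k1
  k2 <- rowMeans(cent^2)
  k3 <- rowMeans(cent^3)
  k4 <- rowMeans(cent^4) - 3 * k2^2
  pvals <- apply(vals, 1L, function(v) {
    if (max(v) - min(v) < 1e-12) return(NA_real_)   # constant: test undefined
    stats::shapiro.test(v)$p.value
  })
  rej <- !is.na(pvals) & pvals < alpha
  frac_normal <- mean(!rej)
  list(pixels = data.frame(index = idx, shapiro_p = pvals, reject = rej,
                           k1 = k1, k2 = k2, k3 = k3, k4 = k4),
       fraction_normal = frac_normal, alpha = alpha)
}
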