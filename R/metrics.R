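# Image-similarity layer: 3D/2D SSIM with a uniform window, PSNR, a
# perceptual feature distance, boundary SSIM on Sobel edge maps, and the
# slice-consistency SSIM, plus Wilcoxon signed-rank model comparison.

# separable sliding-window mean of a 2D/3D array; entries within pad of the
# border hold partial sums and are cropped by the caller
box_mean_nd <- function(x, w) {
  d <- dim(x)
  h <- (w - 1L) %/% 2L
  out <- x
  for (ax in seq_along(d)) {
    acc <- array(0, dim(out))
    for (s in -h:h) {
      idx_src <- (1 + max(0, s)):(d[ax] + min(0, s))
      idx_dst <- idx_src - s
      sl_src <- lapply(seq_along(d), function(k) if (k == ax) idx_src else seq_len(d[k]))
      sl_dst <- lapply(seq_along(d), function(k) if (k == ax) idx_dst else seq_len(d[k]))
      acc_part <- do.call(`[`, c(list(out), sl_src, list(drop = FALSE)))
      ref <- do.call(`[`, c(list(acc), sl_dst, list(drop = FALSE)))
      acc <- do.call(`[<-`, c(list(acc), sl_dst, list(value = ref + acc_part)))
    }
    out <- acc / w
  }
  out
}

crop_pad <- function(x, pad) {
  d <- dim(x)
  sl <- lapply(d, function(n) (pad + 1L):(n - pad))
  do.call(`[`, c(list(x), sl, list(drop = FALSE)))
}

# local-SSIM map with uniform window and sample-covariance normalization
# (N/(N-1)); matches the standard reference formulation, window fully inside
ssim_map <- function(a, b, win = 7L, K1 = 0.01, K2 = 0.03, data_range = 1) {
  stop_if_not(all(dim(a) == dim(b)), "shape mismatch between the two images")
  if (any(dim(a) < win)) {
    stop("every image dimension must be >= the SSIM window (", win, ")", call. = FALSE)
  }
  NP <- win^length(dim(a))
  cov_norm <- NP / (NP - 1)
  ux <- box_mean_nd(a, win)
  uy <- box_mean_nd(b, win)
  uxx <- box_mean_nd(a * a, win)
  uyy <- box_mean_nd(b * b, win)
  uxy <- box_mean_nd(a * b, win)
  vx <- cov_norm * (uxx - ux * ux)
  vy <- cov_norm * (uyy - uy * uy)
  vxy <- cov_norm * (uxy - ux * uy)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  crop_pad(S, (win - 1L) %/% 2L)
}

as_arr3 <- function(v) if (inherits(v, "volume")) v$data else v

#' Structural similarity between normalized 3D volumes
#'
#' Mean local SSIM over the full 3D volume (window 7, uniform weights,
#' K1 = 0.01, K2 = 0.03, data range 1), reported as a percentage. Computed
#' volumetrically rather than as a slice-wise average so inter-slice
#' inconsistencies lower the score. An optional mask restricts the average of
#' the local SSIM map to brain voxels.
#'
#' @param a,b [volume()]s or (S, H, W) arrays on [0, 1]; equal shapes, every
#'   dimension >= 7.
#' @param mask optional logical array (same shape) for a masked average.
#' @return SSIM in [0, 100] (percent).
#' @export
ssim3d <- function(a, b, mask = NULL) {
  aa <- as_arr3(a); bb <- as_arr3(b)
  S <- ssim_map(aa, bb)
  if (is.null(mask)) return(100 * mean(S))
  m <- crop_pad(array(as.logical(mask), dim(aa)), 3L)
  stop_if_not(any(m), "mask is empty after window cropping")
  100 * mean(S[m])
}

ssim2d <- function(a, b) mean(ssim_map(a, b))

#' Peak signal-to-noise ratio for normalized volumes
#'
#' `10 log10(peak^2 / MSE)` with peak 1 for min-max normalized data;
#' identical inputs return `Inf` (handled, not an error).
#'
#' @param a,b [volume()]s or arrays on [0, 1].
#' @return PSNR in dB.
#' @export
psnr <- function(a, b) {
  mse <- mean((as_arr3(a) - as_arr3(b))^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

#' Perceptual feature distance between slices of two volumes
#'
#' For each axial slice pair, features `phi_l` are extracted at a set of
#' layers and the distance is
#' `sum_l (1/(H_l W_l)) sum_{h,w} || w_l * (phi_l(y1) - phi_l(y2)) ||^2`,
#' then averaged over slices. Zero iff the feature maps agree; lower is more
#' similar. The extractor is pluggable: the default is a small fixed-seed
#' random convolutional extractor, so no pretrained weights are required;
#' any extractor with the same interface (e.g. wrapping a pretrained
#' network's features) can be substituted.
#'
#' @param a,b [volume()]s or (S, H, W) arrays.
#' @param fx a [feature_extractor()].
#' @return nonnegative scalar distance.
#' @export
lpips_distance <- function(a, b, fx = NULL) {
  aa <- as_arr3(a); bb <- as_arr3(b)
  stop_if_not(all(dim(aa) == dim(bb)), "shape mismatch")
  if (is.null(fx)) fx <- random_feature_extractor(image_size = dim(aa)[2])
  d <- dim(aa)
  ab <- array(0, c(d[2], d[3], 2L * d[1], 1L))
  for (s in seq_len(d[1])) {
    ab[, , s, 1L] <- aa[s, , ]
    ab[, , d[1] + s, 1L] <- bb[s, , ]
  }
  fa <- fx$extract(ab)
  total <- 0
  for (l in seq_along(fa)) {
    f <- fa[[l]]
    df <- f[, , seq_len(d[1]), , drop = FALSE] - f[, , d[1] + seq_len(d[1]), , drop = FALSE]
    wl <- fx$weights[[l]]
    stop_if_not(length(wl) == dim(df)[4], "extractor weights do not match feature channels")
    wdf <- df * aperm(array(wl, c(dim(df)[4], dim(df)[1:3])), c(2, 3, 4, 1))
    total <- total + sum(wdf^2) / (dim(df)[1] * dim(df)[2] * d[1])
  }
  total
}

#' Pluggable feature extractor for the perceptual distance
#'
#' @param extract function mapping an (H, W, N, 1) slice batch to a list of
#'   (H_l, W_l, N, C_l) feature arrays.
#' @param weights list of nonnegative per-channel weight vectors, one per
#'   layer.
#' @return a `feature_extractor`.
#' @export
feature_extractor <- function(extract, weights) {
  for (w in weights) stop_if_not(all(w >= 0), "feature weights must be nonnegative")
  structure(list(extract = extract, weights = weights), class = "feature_extractor")
}

#' @rdname feature_extractor
#' @details `identity_feature_extractor()` returns the image itself as the
#'   single feature layer with unit weight, under which the distance reduces
#'   to the mean squared pixel difference.
#' @export
identity_feature_extractor <- function() {
  feature_extractor(extract = function(x) list(x), weights = list(1))
}

#' @rdname feature_extractor
#' @param seed,widths,image_size configuration of the fixed-seed random
#'   convolutional extractor: each stage is conv3x3 -> SiLU -> 2x2 average
#'   pool, and features are taken after every stage.
#' @export
random_feature_extractor <- function(seed = 7L, widths = c(8L, 16L), image_size = 32L) {
  layers <- list()
  weights <- list()
  with_seed(seed, {
    cin <- 1L
    for (w in widths) {
      layers[[length(layers) + 1L]] <- list(
        W = array(stats::rnorm(9 * cin * w, sd = sqrt(2 / (9 * cin))), c(3, 3, cin, w)),
        b = numeric(w))
      weights[[length(weights) + 1L]] <- stats::runif(w, 0.5, 1.5)
      cin <- w
    }
  })
  extract <- function(x) {
    feats <- list()
    h <- x
    for (l in seq_along(layers)) {
      h <- conv3_fwd(h, layers[[l]]$W, layers[[l]]$b)$out
      h <- .silu_infer_cpp(h)
      feats[[l]] <- h
      h <- pool2_fwd(h)
    }
    feats
  }
  feature_extractor(extract, weights)
}

# Sobel gradient magnitude per axial slice; edge-replicated padding so an
# additive intensity shift leaves the edge map exactly unchanged
sobel_mag <- function(vol) {
  d <- dim(vol)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)     # d/drow
  ky <- t(kx)
  out <- array(0, d)
  for (s in seq_len(d[1])) {
    sl <- vol[s, , ]
    p <- sl[c(1, 1:d[2], d[2]), c(1, 1:d[3], d[3])]
    gx <- matrix(0, d[2], d[3]); gy <- matrix(0, d[2], d[3])
    for (i in 1:3) for (j in 1:3) {
      blk <- p[i:(i + d[2] - 1L), j:(j + d[3] - 1L)]
      gx <- gx + kx[i, j] * blk
      gy <- gy + ky[i, j] * blk
    }
    out[s, , ] <- sqrt(gx^2 + gy^2)
  }
  out
}

#' Boundary SSIM: structural similarity of edge maps
#'
#' Applies a slice-wise Sobel filter to both volumes, renormalizes both
#' gradient-magnitude maps jointly to [0, 1] (shared maximum, preserving
#' relative edge strength), and computes [ssim3d()] on the edge volumes.
#' Emphasizes fidelity at tissue boundaries; invariant to an additive
#' intensity shift of either input.
#'
#' @inheritParams ssim3d
#' @return BSSIM in [0, 100] (percent).
#' @export
bssim <- function(a, b, mask = NULL) {
  ea <- sobel_mag(as_arr3(a))
  eb <- sobel_mag(as_arr3(b))
  mx <- max(ea, eb)
  if (mx > 0) { ea <- ea / mx; eb <- eb / mx }
  ssim3d(ea, eb, mask = mask)
}

#' Slice-consistency SSIM
#'
#' Compares the profiles of consecutive-slice similarity:
#' `100 * (1 - (1/(N-1)) sum_i |SSIM(Y1_i, Y1_{i+1}) - SSIM(Y2_i, Y2_{i+1})|)`
#' using 2D SSIM between adjacent axial slices. Sudden inter-slice changes in
#' one volume but not the other lower the score; 100 means the inter-slice
#' difference profiles match exactly (even if the volumes differ).
#'
#' @param a,b [volume()]s or (S, H, W) arrays with the same number (>= 2) of
#'   slices, H and W >= 7.
#' @return SCSSIM in percent (<= 100).
#' @export
scssim <- function(a, b) {
  aa <- as_arr3(a); bb <- as_arr3(b)
  stop_if_not(all(dim(aa) == dim(bb)), "shape mismatch")
  N <- dim(aa)[1]
  if (N < 2L) stop("SCSSIM needs at least 2 slices", call. = FALSE)
  p1 <- vapply(seq_len(N - 1L), function(i) ssim2d(aa[i, , ], aa[i + 1L, , ]), numeric(1))
  p2 <- vapply(seq_len(N - 1L), function(i) ssim2d(bb[i, , ], bb[i + 1L, , ]), numeric(1))
  100 * (1 - mean(abs(p1 - p2)))
}

#' Per-subject metric report
#'
#' @param rows data frame with columns `subject_id`, `model_tag`, `metric`,
#'   `value` (long format), e.g. built by the experiment runner.
#' @param metric metric name to aggregate.
#' @return data frame of per-model mean and SD.
#' @export
metric_summary <- function(rows, metric) {
  sub <- rows[rows$metric == metric, ]
  agg <- stats::aggregate(value ~ model_tag, data = sub,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  data.frame(model_tag = agg$model_tag, mean = agg$value[, "mean"],
             sd = agg$value[, "sd"])
}

#' Pairwise Wilcoxon signed-rank model comparison with a best-set rule
#'
#' For every ordered model pair, a one-sided paired Wilcoxon signed-rank test
#' of "A better than B" on per-subject values (zero differences dropped, as
#' is standard for the signed-rank statistic). A model belongs to the best
#' set iff no other model is significantly better than it at the given level,
#' which allows several models to share the title when they are statistically
#' indistinguishable. Invariant to subject ordering.
#'
#' @param rows long-format data frame (`subject_id`, `model_tag`, `metric`,
#'   `value`) with paired per-subject values for every model.
#' @param metric metric to compare on.
#' @param higher_is_better direction of "better" (FALSE for error metrics).
#' @param alpha significance level.
#' @return list with the pairwise p-value matrix (`p[a, b]` = p-value of "a
#'   better than b") and `best` (character vector of best-set models).
#' @export
compare_models <- function(rows, metric, higher_is_better = TRUE, alpha = 0.05) {
  sub <- rows[rows$metric == metric, ]
  models <- sort(unique(sub$model_tag))
  subjects <- sort(unique(sub$subject_id))
  vals <- matrix(NA_real_, length(subjects), length(models),
                 dimnames = list(subjects, models))
  for (i in seq_len(nrow(sub))) {
    vals[sub$subject_id[i], sub$model_tag[i]] <- sub$value[i]
  }
  if (any(is.na(vals))) stop("unpaired rows: every subject needs every model", call. = FALSE)
  p <- matrix(NA_real_, length(models), length(models),
              dimnames = list(models, models))
  for (a in models) for (b in models) {
    if (a == b) next
    da <- vals[, a]; db <- vals[, b]
    diffs <- if (higher_is_better) da - db else db - da
    diffs <- diffs[diffs != 0]
    p[a, b] <- if (length(diffs) == 0) 1 else
      suppressWarnings(stats::wilcox.test(diffs, alternative = "greater",
                                          exact = FALSE)$p.value)
  }
  best <- models[vapply(models, function(m) {
    all(p[setdiff(models, m), m] >= alpha, na.rm = TRUE)
  }, logical(1))]
  list(p = p, best = best, alpha = alpha)
}
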