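# the similarity-metric layer: identity values, closed forms, reference
# agreement and the Wilcoxon best-set rule

rand_vol <- function(seed, d = c(8, 16, 16)) {
  set.seed(seed)
  array(runif(prod(d)), d)
}

skimage_ssim <- function(a, b) {
  fa <- tempfile(fileext = ".bin"); fb <- tempfile(fileext = ".bin")
  writeBin(as.numeric(a), fa); writeBin(as.numeric(b), fb)
  d <- dim(a)
  out <- system2("python", c("-c", shQuote(sprintf(paste0(
    "import numpy as np; from skimage.metrics import structural_similarity as ss;",
    "a=np.fromfile('%s').reshape((%d,%d,%d),order='F');",
    "b=np.fromfile('%s').reshape((%d,%d,%d),order='F');",
    "print('%%.12f' %% ss(a,b,win_size=7,data_range=1.0))"),
    fa, d[1], d[2], d[3], fb, d[1], d[2], d[3]))), stdout = TRUE)
  as.numeric(out)
}

test_that("identity inputs give the metric layer's perfect scores", {
  a <- rand_vol(1)
  expect_equal(ssim3d(a, a), 100)
  expect_identical(psnr(a, a), Inf)
  expect_equal(lpips_distance(a, a, identity_feature_extractor()), 0)
  expect_equal(bssim(a, a), 100)
  expect_equal(scssim(a, a), 100)
})

test_that("ssim3d agrees with an independent reference implementation", {
  for (seed in 1:20) {
    a <- rand_vol(seed)
    set.seed(seed + 1000)
    b <- pmin(pmax(a + array(rnorm(length(a), sd = runif(1, 0.02, 0.3)),
                             dim(a)), 0), 1)
    expect_equal(ssim3d(a, b) / 100, skimage_ssim(a, b), tolerance = 1e-6,
                 label = paste("ssim seed", seed))
  }
  # binary phantom versus its inversion
  set.seed(3)
  ph <- array(as.numeric(array(runif(8 * 16 * 16), c(8, 16, 16)) > 0.5), c(8, 16, 16))
  expect_equal(ssim3d(ph, 1 - ph) / 100, skimage_ssim(ph, 1 - ph), tolerance = 1e-6)
})

test_that("jointly translating both inputs barely moves ssim3d", {
  # smooth torus-periodic pattern; a circular shift of BOTH volumes changes
  # only which windows fall inside the cropped interior
  g <- seq(0, 2 * pi, length.out = 17)[1:16]
  base <- outer(sin(g), cos(2 * g))
  a <- array(0, c(8, 16, 16)); b <- a
  for (s in 1:8) {
    a[s, , ] <- (base * sin(2 * pi * s / 8) + 1) / 2
    b[s, , ] <- pmin(pmax(a[s, , ] + 0.1 * outer(cos(g), sin(g)), 0), 1)
  }
  sh <- function(v, k) v[, c((k + 1):16, 1:k), c((k + 1):16, 1:k)]
  expect_equal(ssim3d(sh(a, 5), sh(b, 5)), ssim3d(a, b), tolerance = 2e-2)
  expect_error(ssim3d(a, b[, 1:8, ]), "shape")
  expect_error(ssim3d(array(0, c(3, 16, 16)), array(0, c(3, 16, 16))), "window")
})

test_that("psnr follows its closed form and log law", {
  a <- array(0, c(2, 8, 8))
  b <- a; b[] <- 0.1            # MSE = 0.01 at peak 1
  expect_equal(psnr(a, b), 20)
  b2 <- a; b2[] <- 0.1 / sqrt(2)  # half the MSE
  expect_equal(psnr(a, b2) - psnr(a, b), 10 * log10(2), tolerance = 1e-10)
})

test_that("the perceptual distance degenerates, symmetrizes and rejects mismatch", {
  a <- rand_vol(5); b <- rand_vol(6)
  fx_id <- identity_feature_extractor()
  expect_equal(lpips_distance(a, b, fx_id), mean((a - b)^2), tolerance = 1e-12)
  fx <- random_feature_extractor(seed = 2, image_size = 16)
  expect_equal(lpips_distance(a, b, fx), lpips_distance(b, a, fx), tolerance = 1e-12)
  expect_gt(lpips_distance(a, b, fx), 0)
  bad <- feature_extractor(extract = function(x) list(x),
                           weights = list(rep(1, 5)))
  expect_error(lpips_distance(a, b, bad), "channels")
  expect_error(feature_extractor(function(x) list(x), list(c(-1, 1))),
               "nonnegative")
})

test_that("bssim ignores additive shifts and penalizes blur more than crisp noise", {
  s <- generate_subject(clean_spec(image_size = 16, n_slices = 8), 4)
  a <- s$volumes$t1like$data
  expect_equal(bssim(a, a + 0.17), 100)
  blur <- a
  for (k in 1:8) {
    p <- matrix(0, 18, 18); p[2:17, 2:17] <- a[k, , ]
    blur[k, , ] <- (p[1:16, 2:17] + p[3:18, 2:17] + p[2:17, 1:16] +
                      p[2:17, 3:18] + 4 * p[2:17, 2:17]) / 8
  }
  set.seed(8)
  tiny_noise <- pmin(pmax(a + array(rnorm(length(a), sd = 1e-4), dim(a)), 0), 1)
  expect_lt(bssim(a, blur), bssim(a, tiny_noise))
})

test_that("scssim depends only on the consecutive-slice similarity profiles", {
  s <- generate_subject(clean_spec(image_size = 16, n_slices = 8), 9)
  a <- s$volumes$t1like$data
  # mirroring every slice preserves each consecutive-slice SSIM exactly,
  # so two different volumes share the profile and score 100
  b <- a[, , 16:1]
  expect_false(identical(a, b))
  expect_equal(scssim(a, b), 100, tolerance = 1e-10)
  # replacing one slice with noise lowers the score, more so with more noise
  set.seed(10)
  n1 <- a; n1[4, , ] <- pmin(pmax(a[4, , ] + matrix(rnorm(256, sd = 0.2), 16), 0), 1)
  n2 <- a; n2[4, , ] <- matrix(runif(256), 16)
  expect_lt(scssim(a, n1), 100)
  expect_lt(scssim(a, n2), scssim(a, n1))
  expect_error(scssim(a[1, , , drop = FALSE], b[1, , , drop = FALSE]), "2 slices")
})

test_that("the Wilcoxon best-set rule matches its stated semantics", {
  set.seed(11)
  n <- 20
  base <- runif(n, 80, 95)
  rows <- rbind(
    data.frame(subject_id = sprintf("s%02d", 1:n), model_tag = "a",
               metric = "ssim", value = base),
    data.frame(subject_id = sprintf("s%02d", 1:n), model_tag = "b",
               metric = "ssim", value = base + 1),
    data.frame(subject_id = sprintf("s%02d", 1:n), model_tag = "c",
               metric = "ssim", value = base + 1)
  )
  res <- compare_models(rows, "ssim")
  expect_lt(res$p["b", "a"], 0.05)      # b beats a on every subject
  expect_setequal(res$best, c("b", "c"))  # ties keep both in the best set
  # identical models: no significance, both best
  rows2 <- rows[rows$model_tag != "c", ]
  rows2$value[rows2$model_tag == "b"] <- base
  res2 <- compare_models(rows2, "ssim")
  expect_setequal(res2$best, c("a", "b"))
  # decision invariant to subject order
  res3 <- compare_models(rows[sample(nrow(rows)), ], "ssim")
  expect_identical(res3$best, res$best)
  # error metrics flip the direction
  res4 <- compare_models(transform(rows, metric = "lpips"), "lpips",
                         higher_is_better = FALSE)
  expect_identical(res4$best, "a")
  rows_bad <- rows[-1, ]
  expect_error(compare_models(rows_bad, "ssim"), "unpaired")
})
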