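# synthetic paired-contrast phantom generator

test_that("generation is a pure function of spec and seed", {
  spec <- clean_spec()
  s1 <- generate_subject(spec, 7)
  s2 <- generate_subject(spec, 7)
  expect_identical(s1, s2)
  s3 <- generate_subject(spec, 8)
  expect_false(identical(s1$tissue_map, s3$tissue_map))
})

test_that("subject invariants hold: shapes, mask, normalized range", {
  s <- generate_subject(tiny_spec(), 3)
  expect_identical(dim(s$mask), dim(s$tissue_map))
  expect_identical(s$mask, s$tissue_map != 0L)
  for (v in s$volumes) {
    expect_identical(dim(v$data), dim(s$tissue_map))
    expect_true(all(v$data >= 0 & v$data <= 1))
    expect_true(v$normalized)
  }
})

test_that("equal contrast profiles give identical noiseless volumes", {
  pr <- c(background = 0, csf = 0.2, gray = 0.5, white = 0.8, subcortical = 0.6)
  spec <- phantom_spec(image_size = 16, n_slices = 4,
                       contrast_profiles = list(a = pr, b = pr),
                       noise_sd = 0, intensity_jitter_sd = 0,
                       bias_field_amplitude = 0)
  s <- generate_subject(spec, 5)
  expect_identical(s$volumes$a$data, s$volumes$b$data)
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(image_size = 8), "image_size")
  expect_error(phantom_spec(n_slices = 0), "n_slices")
  expect_error(phantom_spec(noise_sd = -1), ">= 0")
  bad <- list(t1like = c(background = 0.2, csf = 0.2, gray = 0.5,
                         white = 0.8, subcortical = 0.6))
  expect_error(phantom_spec(contrast_profiles = bad), "background")
  expect_error(corruption_spec("sparkle"), "unknown corruption kind")
})

test_that("within-class intensity spread matches the stated noise model", {
  # Monte-Carlo against the additive model: pooled per-class residual SD
  # across subjects ~ sqrt(jitter^2 + noise^2), mildly shrunk by the final
  # min-max rescale
  spec <- phantom_spec(image_size = 16, n_slices = 4, noise_sd = 0.02,
                       intensity_jitter_sd = 0.01, bias_field_amplitude = 0)
  vals <- c()
  for (i in 1:200) {
    s <- generate_subject(spec, 1000 + i)
    vals <- c(vals, s$volumes$t1like$data[s$tissue_map == 3L])
  }
  expected <- sqrt(0.02^2 + 0.01^2)
  expect_equal(sd(vals), expected, tolerance = 0.1)
})

test_that("corruption kinds behave as specified", {
  s <- generate_subject(tiny_spec(), 11)
  expect_identical(corrupt(s, corruption_spec("none")), s)
  low <- corrupt(s, corruption_spec("low_snr", severity = 4, seed = 2))
  expect_gt(var(low$volumes$t1like$data[s$mask]),
            var(s$volumes$t1like$data[s$mask]))
  expect_error(corrupt(low, corruption_spec("zipper")), "already corrupted")
  zip <- corrupt(s, corruption_spec("zipper", severity = 2, seed = 2))
  expect_true(all(zip$volumes$t1like$data >= 0 & zip$volumes$t1like$data <= 1))
})

# independent connected-component labeling (BFS, 4-neighborhood) per slice
label_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  k <- 0L
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] && lab[i, j] == 0L) {
      k <- k + 1L
      queue <- list(c(i, j))
      lab[i, j] <- k
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(m) && q[2] >= 1 && q[2] <= ncol(m) &&
              m[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- k
            queue <- c(queue, list(q))
          }
        }
      }
    }
  }
  k
}

test_that("tumor inserts exactly one connected hyperintense component", {
  spec <- phantom_spec(image_size = 32, n_slices = 6, noise_sd = 0,
                       intensity_jitter_sd = 0, bias_field_amplitude = 0)
  s <- generate_subject(spec, 21)
  tum <- corrupt(s, corruption_spec("tumor", severity = 2, seed = 4))
  blob <- tum$tissue_map == 5L
  areas <- vapply(seq_len(dim(blob)[1]), function(k) sum(blob[k, , ]), numeric(1))
  central <- which.max(areas)
  expect_gte(areas[central], 12)
  expect_identical(label_components(blob[central, , ]), 1L)
  expect_true(all(s$mask[blob]))        # pathology stays inside the brain mask
  # hyperintense in the target contrast, isointense with white matter in input
  expect_gt(mean(tum$volumes$t2like$data[blob]),
            mean(s$volumes$t2like$data[s$tissue_map == 3L]) + 0.3)
  expect_lt(abs(mean(tum$volumes$t1like$data[blob]) -
                  median(s$volumes$t1like$data[s$tissue_map == 3L])), 0.05)
})

test_that("zipper and tumor corruptions raise within-mask intensity (sign test)", {
  spec <- tiny_spec()
  wins_zip <- 0L; wins_tum <- 0L
  n <- 50L
  for (i in seq_len(n)) {
    s <- generate_subject(spec, 3000 + i)
    zc <- corrupt(s, corruption_spec("zipper", severity = 2, seed = i))
    tc <- corrupt(s, corruption_spec("tumor", severity = 2, seed = i))
    wins_zip <- wins_zip + (mean(zc$volumes$t1like$data[s$mask]) >
                              mean(s$volumes$t1like$data[s$mask]))
    wins_tum <- wins_tum + (mean(tc$volumes$t2like$data[s$mask]) >
                              mean(s$volumes$t2like$data[s$mask]))
  }
  expect_lt(binom.test(wins_zip, n, alternative = "greater")$p.value, 0.01)
  expect_lt(binom.test(wins_tum, n, alternative = "greater")$p.value, 0.01)
})

test_that("cohorts count, label and regenerate deterministically", {
  spec <- tiny_spec()
  expect_identical(generate_cohort(spec, 0, 0), list())
  co <- generate_cohort(spec, 10, 2)
  expect_length(co, 10 + 2 * 5)
  kinds <- vapply(co, function(s) s$corruption$kind, "")
  expect_identical(sum(kinds == "none"), 10L)
  expect_identical(as.integer(table(kinds[kinds != "none"])), rep(2L, 5))
  expect_identical(generate_cohort(spec, 3, 1), generate_cohort(spec, 3, 1))
  ids <- vapply(co, function(s) s$subject_id, "")
  expect_identical(anyDuplicated(ids), 0L)
})
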