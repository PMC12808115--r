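# OOD classification from uncertainty scores: ROC/AUC, F1 sweep, isotonic
# calibration and reliability metrics

make_scores <- function(score, label, ids = NULL) {
  ood_scores(ids %||% sprintf("s%03d", seq_along(score)), score, label)
}

test_that("AUC is 1 for separated scores, ~0.5 for independent ones", {
  sep <- make_scores(c(runif(20, 0, 0.4), runif(20, 0.6, 1)),
                     rep(c(0, 1), each = 20))
  expect_equal(roc_auc(sep)$auc, 1)
  set.seed(41)
  indep <- make_scores(runif(2000), rbinom(2000, 1, 0.5))
  expect_equal(roc_auc(indep)$auc, 0.5, tolerance = 0.05)
  expect_error(roc_auc(make_scores(runif(5), rep(1, 5))), "both classes")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(42)
  sc <- make_scores(rnorm(60), rbinom(60, 1, 0.4))
  a1 <- roc_auc(sc)$auc
  sc2 <- sc; sc2$score <- exp(3 * sc$score) + 7
  expect_equal(roc_auc(sc2)$auc, a1, tolerance = 1e-12)
  curve <- roc_auc(sc)$curve
  expect_true(all(diff(curve$fpr) >= 0) && all(diff(curve$tpr) >= 0))
})

test_that("F1 matches hand arithmetic and edge cases", {
  # 10 OOD of which 8 score high, 2 ID score high: TP=8 FP=2 FN=2 at thr 0.5
  sc <- make_scores(c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 2), rep(0.1, 8)),
                    c(rep(1, 10), rep(0, 10)))
  sw <- f1_sweep(sc, thresholds = 0.5)
  expect_equal(sw$curve$f1, 0.8)       # precision 0.8, recall 0.8
  # threshold below all scores: recall 1, precision = prevalence
  low <- f1_sweep(sc, thresholds = 0)
  prevalence <- 0.5
  expect_equal(low$curve$f1, 2 * prevalence / (prevalence + 1))
})

test_that("max F1 equals exhaustive search over all midpoint thresholds", {
  set.seed(43)
  for (rep_ in 1:5) {
    sc <- make_scores(round(runif(40), 2), rbinom(40, 1, 0.5))
    if (length(unique(sc$label)) < 2) next
    got <- f1_sweep(sc)
    u <- sort(unique(sc$score))
    cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
    brute <- max(vapply(cand, function(th) {
      pred <- as.integer(sc$score >= th)
      tp <- sum(pred & sc$label); fp <- sum(pred & !sc$label)
      fn <- sum(!pred & sc$label)
      if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }, numeric(1)))
    expect_equal(got$max_f1, brute, tolerance = 1e-12)
  }
})

test_that("reliability metrics reproduce their closed forms", {
  perfect <- make_scores(c(rep(0, 10), rep(1, 10)), rep(c(0, 1), each = 10))
  perfect$prob <- perfect$score
  r <- reliability_metrics(perfect)
  expect_equal(r$brier, 0)
  expect_equal(r$ece, 0)
  expect_lt(r$nll, 1e-4)
  half <- make_scores(rep(0.5, 40), rep(c(0, 1), 20))
  half$prob <- half$score
  r2 <- reliability_metrics(half)
  expect_equal(r2$brier, 0.25)
  expect_equal(r2$nll, log(2), tolerance = 1e-12)
  expect_equal(r2$ece, 0, tolerance = 1e-12)    # conf 0.5 = acc 0.5
  expect_error(reliability_metrics(perfect[0, ]), "empty")
})

test_that("ECE matches brute-force binning on a hand-built set", {
  p <- c(0.05, 0.15, 0.15, 0.45, 0.45, 0.55, 0.75, 0.75, 0.95, 0.95)
  y <- c(0, 0, 1, 0, 1, 1, 1, 0, 1, 1)
  sc <- make_scores(p, y)
  sc$prob <- p
  got <- reliability_metrics(sc, n_bins = 10)$ece
  # manual: bins (0,0.1], (0.1,0.2], ... ; |acc - conf| weighted by count
  manual <- (1 / 10) * abs(0 - 0.05) + (2 / 10) * abs(0.5 - 0.15) +
    (2 / 10) * abs(0.5 - 0.45) + (1 / 10) * abs(1 - 0.55) +
    (2 / 10) * abs(0.5 - 0.75) + (2 / 10) * abs(1 - 0.95)
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("isotonic calibration is near-identity for calibrated scores", {
  set.seed(44)
  n <- 1500
  p_val <- runif(n); p_test <- runif(n)
  val <- make_scores(p_val, rbinom(n, 1, p_val), ids = sprintf("v%03d", 1:n))
  test <- make_scores(p_test, rbinom(n, 1, p_test), ids = sprintf("t%03d", 1:n))
  val$prob <- val$score; test$prob <- test$score
  before <- reliability_metrics(test)$ece
  cal <- calibrate_isotonic(val, test)
  after <- reliability_metrics(cal$calibrated)$ece
  expect_lt(after, before + 0.01)
  expect_true(all(cal$calibrated$prob >= 0 & cal$calibrated$prob <= 1))
  expect_true(all(diff(cal$map$prob) >= 0))      # monotone map
})

test_that("calibration fixes a miscalibrated score set and preserves ranking", {
  set.seed(45)
  n <- 400
  truth <- runif(n)
  squash <- 0.4 + 0.2 * truth            # compressed, overconfident-at-ends
  val <- make_scores(squash, rbinom(n, 1, truth), ids = sprintf("v%03d", 1:n))
  truth2 <- runif(n)
  test <- make_scores(0.4 + 0.2 * truth2, rbinom(n, 1, truth2),
                      ids = sprintf("t%03d", 1:n))
  raw <- test; raw$prob <- raw$score
  cal <- calibrate_isotonic(val, test)
  expect_lt(reliability_metrics(cal$calibrated)$ece,
            reliability_metrics(raw)$ece)
  # a monotone map cannot change the AUC
  a_raw <- roc_auc(test)$auc
  cal_sc <- cal$calibrated; cal_sc$score <- cal_sc$prob
  expect_lt(abs(roc_auc(cal_sc)$auc - a_raw), 0.02)  # ties from flat segments only
})

test_that("calibration protocol guards its preconditions", {
  val <- make_scores(runif(20), rep(c(0, 1), 10), ids = sprintf("v%02d", 1:20))
  test <- make_scores(runif(10), rep(c(0, 1), 5), ids = sprintf("v%02d", 1:10))
  expect_error(calibrate_isotonic(val, test), "disjoint")
  test2 <- make_scores(runif(10), rep(c(0, 1), 5), ids = sprintf("t%02d", 1:10))
  expect_error(calibrate_isotonic(val, test2, n_folds = 11), "folds")
})
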