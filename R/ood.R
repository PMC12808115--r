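# OOD detection from scalar uncertainty scores: ROC/AUC, threshold-swept F1,
# isotonic calibration with cross-validation, and reliability metrics.

#' Build an OOD score set
#'
#' @param subject_id subject identifiers.
#' @param score raw uncertainty scores (e.g. [sigma_hat()] values).
#' @param label 0 for in-distribution, 1 for OOD (or a corruption-kind string;
#'   anything other than `"none"`/`0` counts as OOD).
#' @param model_tag generating model.
#' @return an `ood_scores` data frame with columns `subject_id`, `score`,
#'   `label` (0/1), `kind`, `model_tag`.
#' @export
ood_scores <- function(subject_id, score, label, model_tag = "") {
  kind <- as.character(label)
  y <- ifelse(kind %in% c("0", "none", "id", "ID"), 0L, 1L)
  structure(data.frame(subject_id = subject_id, score = as.numeric(score),
                       label = y, kind = kind, model_tag = model_tag,
                       stringsAsFactors = FALSE),
            class = c("ood_scores", "data.frame"))
}

#' ROC curve and AUC for an OOD score set
#'
#' Sweeps the classification threshold over all score values; AUC is the
#' rank-based (Mann-Whitney) area with midpoint handling of ties, equal to
#' the trapezoidal area under the ROC curve and invariant under any strictly
#' increasing transform of the scores.
#'
#' @param scores an [ood_scores()] data frame (both classes present).
#' @return list with `curve` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(scores) {
  y <- scores$label
  s <- scores$score
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(s)                       # midpoint ranks under ties
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  tpr <- vapply(thr, function(th) mean(s[y == 1] >= th), numeric(1))
  fpr <- vapply(thr, function(th) mean(s[y == 0] >= th), numeric(1))
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

f1_at <- function(y, s, th) {
  pred <- as.integer(s >= th)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

#' F1 score swept over classification thresholds
#'
#' Binarizes the scores at each threshold (score >= threshold flags OOD) and
#' reports the F1 (harmonic mean of precision and recall) curve and its
#' maximum.
#'
#' @param scores an [ood_scores()] data frame.
#' @param thresholds threshold grid; defaults to all midpoints between
#'   consecutive distinct scores (plus the extremes), which realizes every
#'   possible confusion table.
#' @return list with `curve` (threshold, f1), `max_f1`, `best_threshold`.
#' @export
f1_sweep <- function(scores, thresholds = NULL) {
  y <- scores$label
  s <- scores$score
  if (sum(y == 1) == 0 || sum(y == 0) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  if (is.null(thresholds)) {
    u <- sort(unique(s))
    thresholds <- c(min(u) - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, max(u) + 1)
  }
  f1 <- vapply(thresholds, function(th) f1_at(y, s, th), numeric(1))
  k <- which.max(f1)
  list(curve = data.frame(threshold = thresholds, f1 = f1),
       max_f1 = f1[k], best_threshold = thresholds[k])
}

# evaluate a monotone calibration map (piecewise-linear in the fitted knots,
# clamped outside the fitted range)
apply_calibration <- function(map, score) {
  sn <- (score - map$score_min) / (map$score_rng %||% 1)
  p <- stats::approx(map$grid, map$prob, xout = sn, rule = 2)$y
  pmin(pmax(p, 0), 1)
}

#' Isotonic-regression calibration of OOD scores with cross-validation
#'
#' Learns a monotone nondecreasing map from (min-max normalized) raw scores
#' to empirical OOD probabilities. Following the validation protocol, the
#' in-distribution subjects of the validation set are split into k folds;
#' each fold's training part is combined with a randomly selected, equally
#' sized subset of OOD validation subjects (balanced coverage), an isotonic
#' fit (pool-adjacent-violators via [stats::isoreg()]) is computed, and the
#' per-fold maps are averaged on a fixed score grid into a single monotone
#' map. The map is then applied to the held-out test scores only, so all
#' reported reliability metrics correspond to unseen subjects.
#'
#' @param val_scores validation [ood_scores()] (fits the map).
#' @param test_scores test [ood_scores()] (disjoint subjects; calibrated).
#' @param n_folds folds over the ID validation subjects.
#' @param ood_subset_seed seed for the balanced OOD subset draw.
#' @return list with `map` (a `calibration_map`), `calibrated`
#'   (`test_scores` with a `prob` column), and `val_calibrated`.
#' @export
calibrate_isotonic <- function(val_scores, test_scores, n_folds = 5L,
                               ood_subset_seed = 1L) {
  stop_if_not(!any(test_scores$subject_id %in% val_scores$subject_id),
              "validation and test subjects must be disjoint")
  id_idx <- which(val_scores$label == 0)
  ood_idx <- which(val_scores$label == 1)
  stop_if_not(length(id_idx) > 0 && length(ood_idx) > 0,
              "validation set needs both classes")
  if (n_folds > length(id_idx)) {
    stop("more folds than in-distribution validation subjects", call. = FALSE)
  }
  smin <- min(val_scores$score)
  srng <- max(val_scores$score) - smin
  if (srng == 0) srng <- 1
  norm_s <- (val_scores$score - smin) / srng
  grid <- seq(0, 1, length.out = 101L)
  acc <- matrix(0, 0, length(grid))
  with_seed(ood_subset_seed, {
    folds <- sample(rep_len(seq_len(n_folds), length(id_idx)))
    for (f in seq_len(n_folds)) {
      tr_id <- id_idx[folds != f]
      n_ood <- min(length(ood_idx), max(length(tr_id), 1L))
      tr_ood <- sample(ood_idx, n_ood)
      tr <- c(tr_id, tr_ood)
      s <- norm_s[tr]; y <- val_scores$label[tr]
      ord <- order(s)
      iso <- stats::isoreg(s[ord], y[ord])
      fit <- stats::approx(iso$x, iso$yf, xout = grid, rule = 2, ties = mean)$y
      acc <- rbind(acc, pmin(pmax(fit, 0), 1))
    }
  })
  prob <- colMeans(acc)
  prob <- cummax(prob)            # enforce monotonicity after averaging
  map <- structure(list(grid = grid, prob = prob, score_min = smin,
                        score_rng = srng, n_folds = n_folds),
                   class = "calibration_map")
  test_out <- test_scores
  test_out$prob <- apply_calibration(map, test_scores$score)
  val_out <- val_scores
  val_out$prob <- apply_calibration(map, val_scores$score)
  list(map = map, calibrated = test_out, val_calibrated = val_out)
}

#' Reliability metrics for probabilistic binary scores
#'
#' ECE with M equal-width bins over [0, 1]
#' (`sum_m (n_m/N) |acc(m) - conf(m)|` where confidence is the predicted OOD
#' probability), the Brier score `(1/N) sum (p_i - y_i)^2`, and the negative
#' log-likelihood with probabilities clipped away from 0/1.
#'
#' @param scores an [ood_scores()] data frame with a `prob` column (or raw
#'   scores in [0, 1] via `prob_col = "score"`).
#' @param n_bins number of ECE bins.
#' @param prob_col column holding the probabilities.
#' @param clip probability clipping for the log loss.
#' @return list with `ece`, `brier`, `nll`.
#' @export
reliability_metrics <- function(scores, n_bins = 10L, prob_col = "prob",
                                clip = 1e-6) {
  stop_if_not(nrow(scores) > 0, "empty score set")
  p <- scores[[prob_col]]
  stop_if_not(all(p >= 0 & p <= 1), "probabilities must lie in [0, 1]")
  y <- scores$label
  N <- length(p)
  bin <- pmin(pmax(ceiling(p * n_bins), 1L), n_bins)
  ece <- 0
  for (m in seq_len(n_bins)) {
    in_bin <- bin == m
    nm <- sum(in_bin)
    if (nm == 0) next
    ece <- ece + (nm / N) * abs(mean(y[in_bin]) - mean(p[in_bin]))
  }
  pc <- pmin(pmax(p, clip), 1 - clip)
  nll <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  brier <- mean((p - y)^2)
  list(ece = ece, brier = brier, nll = nll)
}
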