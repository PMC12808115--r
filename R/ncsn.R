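#' NCSN forward noising
#'
#' Variance-exploding perturbation `y_t = y_0 + sqrt(beta[t]) * eps` with
#' `eps ~ N(0, I)`.
#'
#' @param y0 clean array (any shape).
#' @param t step index in 1..T.
#' @param schedule an `ncsn_geometric` [noise_schedule()].
#' @param eps standard-normal array matching `y0`; drawn if `NULL`.
#' @return the noised array.
#' @export
ncsn_noise <- function(y0, t, schedule, eps = NULL) {
  t <- check_t(t, schedule$T)
  if (is.null(eps)) eps <- array(stats::rnorm(length(y0)), dim(y0) %||% length(y0))
  y0 + sqrt(schedule$beta[t]) * eps
}

#' Denoising-score-matching loss (Monte-Carlo estimate)
#'
#' Estimates `(1/2T) sum_t beta[t] E |s(y_t, x, t) + (y_t - y_0)/beta[t]|^2`
#' with one uniformly sampled step per example (an unbiased single-sample
#' estimator of the sum, up to the uniform-sampling constant):
#' `(1/2) mean_i beta[t_i] * |s_i + (y_t - y_0)/beta[t_i]|^2`, the squared
#' norm summed over pixels. Zero exactly when `s` is the analytic optimum
#' `-(y_t - y_0)/beta[t]`.
#'
#' @param score_fn function `(y_t, x, t_vec) -> score array` (H, W, N).
#' @param x,y0 input-contrast and clean target slices, arrays (H, W, N).
#' @param schedule an `ncsn_geometric` [noise_schedule()].
#' @param t,eps optional fixed step indices (length N) and noise field;
#'   drawn when `NULL`.
#' @return scalar loss (>= 0).
#' @export
ncsn_loss <- function(score_fn, x, y0, schedule, t = NULL, eps = NULL) {
  d <- dim(y0)
  stop_if_not(length(d) == 3 && d[3] >= 1, "y0 must be (H, W, N) with N >= 1")
  N <- d[3]
  if (is.null(t)) t <- sample.int(schedule$T, N, replace = TRUE)
  t <- check_t(t, schedule$T)
  if (is.null(eps)) eps <- array(stats::rnorm(length(y0)), d)
  bet <- schedule$beta[t]
  sb <- rep(sqrt(bet), each = d[1] * d[2])
  yt <- y0 + array(sb, d) * eps
  s <- score_fn(yt, x, t)
  resid <- s + (yt - y0) / array(rep(bet, each = d[1] * d[2]), d)
  rm <- resid * resid
  dim(rm) <- c(d[1] * d[2], N)
  mean(bet * colSums(rm)) / 2
}

#' Train a conditional noise-conditional score network
#'
#' Learns the score of the conditional target distribution across noise
#' levels. Internally the backbone predicts the clean image
#' `y0_hat(y_t, x, t)` and the score is recovered as
#' `s(y_t, x, t) = (y0_hat - y_t) / beta[t]`; the per-level minimizer is the
#' same conditional expectation as for the raw score-matching objective, but
#' the clean-image target supervises the anatomy equally at every noise
#' level, and a Langevin step's error stays bounded by the clean-image error
#' (`gamma_t * score_error = (gamma_t/beta_t) * y0_error`) instead of being
#' amplified at small variances.
#'
#' @param data a `paired_slice_dataset` (training split).
#' @param schedule an `ncsn_geometric` [noise_schedule()]; when `beta_max`
#'   is `NULL` in `cfg`, the maximal pairwise distance between a subsample of
#'   training targets sets `sqrt(beta_max)`.
#' @param steps,batch_size,lr optimizer settings.
#' @param base_width,depth backbone size.
#' @param seed RNG seed (initialization, batching, noise draws).
#' @return an `ncsn_model` with the trained net, schedule and loss history.
#' @export
train_ncsn <- function(data, schedule = NULL, steps = 800L, batch_size = 8L,
                       lr = 1e-3, base_width = 8L, depth = 2L, seed = 1L) {
  np <- n_pairs(data)
  stop_if_not(np > 0, "empty training dataset")
  hw <- data$slice_shape
  if (is.null(schedule)) {
    dmax <- max_pairwise_distance(data$y)
    schedule <- noise_schedule("ncsn_geometric", T = 100L, beta_min = 1e-4,
                               beta_max = max(dmax^2, 1))
  }
  cfg <- backbone_config(in_channels = 2L, out_channels = 1L,
                         base_width = base_width, depth = depth,
                         time_conditioning = TRUE, image_size = hw[1],
                         input_gate = TRUE)
  net <- build_backbone(cfg, seed = seed)
  opt <- adam_new(net$params, lr = lr)
  hist <- numeric(steps)
  with_seed(seed + 1L, {
    for (s in seq_len(steps)) {
      idx <- sample.int(np, min(batch_size, np))
      y0 <- data$y[, , idx, drop = FALSE]
      x <- data$x[, , idx, drop = FALSE]
      nb <- length(idx)
      # continuous level indices densely cover the noise scales; the scale
      # factor kappa additionally exposes the network to residuals somewhat
      # hotter than the nominal level, which the one-step-per-level annealed
      # sampler produces (its marginal runs slightly above beta[t]); the
      # regression target is the clean image itself, reachable at small noise
      # through the backbone's step-gated input blend
      t <- stats::runif(nb, 1, schedule$T)
      kappa <- stats::runif(nb, 0.7, 2)
      eps <- array(stats::rnorm(length(y0)), dim(y0))
      kf <- array(rep(kappa, each = hw[1] * hw[2]), dim(y0))
      sb <- array(rep(sqrt(sched_beta_at(schedule, t)), each = hw[1] * hw[2]), dim(y0))
      yt <- y0 + kf * sb * eps
      inp <- abind_ch(yt, x)
      tape <- tg_tape()
      out <- backbone_forward(net, inp, t = t, tape = tape)
      loss <- op_sq_residual(tape, out, array(y0, c(dim(y0), 1L)),
                             reduce = "mean")
      tg_zero_grads(net$params)
      tg_backward(tape, loss)
      adam_step(opt)
      hist[s] <- loss$value
    }
  })
  structure(list(net = net, schedule = schedule, loss_history = hist,
                 seed = seed), class = "ncsn_model")
}

# stack two (H, W, N) arrays as channels -> (H, W, N, 2)
abind_ch <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d, 2L))
  out[, , , 1L] <- a
  out[, , , 2L] <- b
  out
}

max_pairwise_distance <- function(y, max_n = 24L) {
  n <- dim(y)[3]
  idx <- if (n > max_n) round(seq(1, n, length.out = max_n)) else seq_len(n)
  m <- 0
  for (i in idx) for (j in idx) {
    if (j <= i) next
    m <- max(m, sqrt(sum((y[, , i] - y[, , j])^2)))
  }
  m
}

# score function wrapper for a trained model; accepts real-valued levels
ncsn_score_fn <- function(model) {
  function(yt, x, t) {
    y0hat <- array(backbone_forward(model$net, abind_ch(yt, x), t = t), dim(yt))
    bet <- array(rep(sched_beta_at(model$schedule, t),
                     each = dim(yt)[1] * dim(yt)[2]), dim(yt))
    (y0hat - yt) / bet
  }
}

#' Sample transformed volumes by annealed Langevin dynamics
#'
#' Runs `y_{t-1} = y_t + gamma[t] * s(y_t, x, t) + sqrt(2 gamma[t]) * eps`
#' from `y_T ~ N(0, beta[T] I)` down to t = 1, independently for each of `n`
#' samples and each slice of the input volume; the final iterate is returned
#' (clipped to [0, 1] for trained models).
#'
#' @param model an `ncsn_model`, or a score function `(y, x, t) -> array` for
#'   oracle chains (no clipping applied then).
#' @param input_volume a [volume()] or (S, H, W) array of the input contrast.
#' @param n number of samples (>= 1).
#' @param lcfg a [langevin_config()]; matched default when `NULL`.
#' @param schedule required when `model` is a bare function.
#' @param seed RNG seed; identical seeds give identical ensembles.
#' @param max_batch largest slice batch processed at once.
#' @return an `mrt_ensemble` (see [ens_summarize()]).
#' @export
ncsn_sample <- function(model, input_volume, n = 20L, lcfg = NULL,
                        schedule = NULL, seed = 1L, max_batch = 64L) {
  stop_if_not(n >= 1, "n must be >= 1")
  oracle <- is.function(model)
  sched <- if (oracle) schedule else model$schedule
  stop_if_not(!is.null(sched), "schedule required for oracle score functions")
  if (is.null(lcfg)) lcfg <- langevin_config(sched)
  score <- if (oracle) model else ncsn_score_fn(model)
  xarr <- if (inherits(input_volume, "volume")) input_volume$data else input_volume
  d <- dim(xarr)
  S <- d[1]; H <- d[2]; W <- d[3]
  total <- S * n
  res <- array(0, c(H, W, total))
  xrep <- array(0, c(H, W, total))
  for (k in seq_len(total)) xrep[, , k] <- xarr[((k - 1) %% S) + 1, , ]
  with_seed(seed, {
    for (st in seq.int(1L, total, by = max_batch)) {
      en <- min(st + max_batch - 1L, total)
      xb <- xrep[, , st:en, drop = FALSE]
      nb <- en - st + 1L
      y <- array(stats::rnorm(H * W * nb, sd = sqrt(sched$beta[sched$T])), c(H, W, nb))
      for (t in seq.int(sched$T, 1L)) {
        g <- lcfg$gamma[t]
        y <- y + g * score(y, xb, rep(t, nb)) +
          sqrt(2 * g) * array(stats::rnorm(length(y)), dim(y))
      }
      res[, , st:en] <- y
    }
  })
  if (!oracle) res <- clip01(res)
  samples_to_ensemble(res, S, n, model_tag = "ncsn",
                      input_ref = if (inherits(input_volume, "volume")) input_volume$subject_id else "")
}

# reshape flat (H, W, S*n) chain output into n volumes and summarize
samples_to_ensemble <- function(res, S, n, model_tag, input_ref) {
  H <- dim(res)[1]; W <- dim(res)[2]
  vols <- vector("list", n)
  for (i in seq_len(n)) {
    v <- array(0, c(S, H, W))
    for (s in seq_len(S)) v[s, , ] <- res[, , (i - 1) * S + s]
    vols[[i]] <- v
  }
  ens_summarize(vols, model_tag = model_tag, input_ref = input_ref)
}
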