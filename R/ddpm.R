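#' DDPM forward noising
#'
#' Variance-preserving perturbation
#' `y_t = sqrt(alpha_bar[t]) * y_0 + sqrt(1 - alpha_bar[t]) * eps`.
#'
#' @param y0 clean array.
#' @param t step index in 1..T.
#' @param schedule a `ddpm_linear` [noise_schedule()].
#' @param eps standard-normal array matching `y0`; drawn if `NULL`.
#' @return the noised array.
#' @export
ddpm_noise <- function(y0, t, schedule, eps = NULL) {
  t <- check_t(t, schedule$T)
  if (is.null(eps)) eps <- array(stats::rnorm(length(y0)), dim(y0) %||% length(y0))
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * y0 + sqrt(1 - ab) * eps
}

#' DDPM training loss (Monte-Carlo estimate)
#'
#' The noise-prediction objective
#' `(1/2T) sum_t E |eta(sqrt(ab_t) y0 + sqrt(1-ab_t) eps, x, t) - eps|^2`
#' estimated with one uniformly sampled step per example:
#' `(1/2) mean_i |eta_i - eps_i|^2` with the squared norm summed over pixels.
#' Exactly zero when `eta` returns the noise used in the perturbation. The
#' hybrid variational term that trains the learned reverse variance is added
#' during training (see [train_ddpm()]), not part of this estimator when
#' `hybrid_loss_weight = 0`.
#'
#' @param eps_fn function `(y_t, x, t_vec) -> predicted-noise array`.
#' @param x,y0 arrays (H, W, N).
#' @param schedule a `ddpm_linear` [noise_schedule()].
#' @param t,eps optional fixed steps / noise.
#' @return scalar loss (>= 0).
#' @export
ddpm_loss <- function(eps_fn, x, y0, schedule, t = NULL, eps = NULL) {
  d <- dim(y0)
  stop_if_not(length(d) == 3 && d[3] >= 1, "y0 must be (H, W, N) with N >= 1")
  N <- d[3]
  if (is.null(t)) t <- sample.int(schedule$T, N, replace = TRUE)
  t <- check_t(t, schedule$T)
  if (is.null(eps)) eps <- array(stats::rnorm(length(y0)), d)
  ab <- array(rep(schedule$alpha_bar[t], each = d[1] * d[2]), d)
  yt <- sqrt(ab) * y0 + sqrt(1 - ab) * eps
  pred <- eps_fn(yt, x, t)
  rm <- (pred - eps)^2
  dim(rm) <- c(d[1] * d[2], N)
  mean(colSums(rm)) / 2
}

# posterior variance (1 - ab_{t-1})/(1 - ab_t) * beta_t, with the t = 1 entry
# (which is 0 and never used by the sampler) replaced for the log-space
# interpolation
ddpm_posterior_var <- function(schedule) {
  ab <- schedule$alpha_bar
  ab_prev <- c(1, ab[-schedule$T])
  pv <- (1 - ab_prev) / (1 - ab) * schedule$beta
  if (schedule$T > 1) pv[1] <- pv[2]
  pv
}

#' Train a conditional DDPM with learned reverse variance
#'
#' Optimizes the noise-prediction loss plus `hybrid_loss_weight` times a
#' variational term that trains the reverse variance
#' `beta_tilde(t) = exp(w_t log beta_t + (1 - w_t) log beta_post_t)`, a
#' log-space interpolation between the forward variance and the posterior
#' variance, with the mean path detached (the variational gradient only
#' reaches the interpolation weights `w_t = sigmoid(v_t)`). Targets are
#' internally mapped to [-1, 1] so the terminal marginal matches N(0, I).
#'
#' @param data a `paired_slice_dataset`.
#' @param schedule a `ddpm_linear` [noise_schedule()]; default T = 100.
#' @param steps,batch_size,lr optimizer settings.
#' @param hybrid_loss_weight weight of the variational variance term.
#' @param base_width,depth backbone size.
#' @param seed RNG seed.
#' @return a `ddpm_model` with net, schedule, learned `beta_tilde` and loss
#'   history.
#' @export
train_ddpm <- function(data, schedule = NULL, steps = 800L, batch_size = 8L,
                       lr = 1e-3, hybrid_loss_weight = 0.001,
                       base_width = 8L, depth = 2L, seed = 1L) {
  np <- n_pairs(data)
  stop_if_not(np > 0, "empty training dataset")
  stop_if_not(hybrid_loss_weight >= 0, "hybrid_loss_weight must be >= 0")
  hw <- data$slice_shape
  if (is.null(schedule)) schedule <- noise_schedule("ddpm_linear", T = 100L)
  cfg <- backbone_config(in_channels = 2L, out_channels = 1L,
                         base_width = base_width, depth = depth,
                         time_conditioning = TRUE, image_size = hw[1])
  net <- build_backbone(cfg, seed = seed)
  opt <- adam_new(net$params, lr = lr)
  Tn <- schedule$T
  v <- numeric(Tn)              # interpolation logits, w = sigmoid(v)
  v_m <- numeric(Tn); v_v <- numeric(Tn); v_t <- 0L
  pv <- ddpm_posterior_var(schedule)
  lbeta <- log(schedule$beta); lpv <- log(pv)
  hist <- numeric(steps)
  m2 <- hw[1] * hw[2]
  with_seed(seed + 1L, {
    for (s in seq_len(steps)) {
      idx <- sample.int(np, min(batch_size, np))
      y0 <- 2 * data$y[, , idx, drop = FALSE] - 1
      x <- data$x[, , idx, drop = FALSE]
      nb <- length(idx)
      t <- sample.int(Tn, nb, replace = TRUE)
      eps <- array(stats::rnorm(length(y0)), dim(y0))
      ab <- array(rep(schedule$alpha_bar[t], each = m2), dim(y0))
      yt <- sqrt(ab) * y0 + sqrt(1 - ab) * eps
      inp <- abind_ch(yt, x)
      tape <- tg_tape()
      out <- backbone_forward(net, inp, t = t, tape = tape)
      # "v" regression target sqrt(ab) eps - sqrt(1-ab) y0: equivalent to the
      # noise-prediction objective through an invertible reparameterization,
      # but the implied eps error is sqrt(ab) * v-error at every level, so
      # reverse-chain updates never amplify the regression error (a raw eps
      # target is noise-dominated at small t and anatomy-starved at large t)
      vtarget <- sqrt(ab) * eps - sqrt(1 - ab) * y0
      loss <- op_sq_residual(tape, out, array(vtarget, c(dim(y0), 1L)), reduce = "mean")
      tg_zero_grads(net$params)
      tg_backward(tape, loss)
      adam_step(opt)
      lossv <- loss$value
      if (hybrid_loss_weight > 0) {
        # variational term: KL between the forward posterior and the reverse
        # Gaussian with interpolated variance; mean path detached, so the
        # gradient w.r.t. each sampled v_t is analytic
        pred <- sqrt(ab) * array(vof(out), dim(y0)) + sqrt(1 - ab) * yt
        gv <- numeric(Tn); klsum <- 0
        for (b in seq_len(nb)) {
          tb <- t[b]
          w <- 1 / (1 + exp(-v[tb]))
          lsig <- w * lbeta[tb] + (1 - w) * lpv[tb]
          sig2 <- exp(lsig)
          ab_t <- schedule$alpha_bar[tb]
          ab_p <- if (tb > 1) schedule$alpha_bar[tb - 1] else 1
          bet <- schedule$beta[tb]
          alp <- schedule$alpha[tb]
          muq <- (sqrt(ab_p) * bet / (1 - ab_t)) * y0[, , b] +
            (sqrt(alp) * (1 - ab_p) / (1 - ab_t)) * yt[, , b]
          mup <- (yt[, , b] - (bet / sqrt(1 - ab_t)) * pred[, , b]) / sqrt(alp)
          mres <- mean((muq - mup)^2)
          kl <- 0.5 * (lsig - lpv[tb] + (pv[tb] + mres) / sig2 - 1)
          klsum <- klsum + kl / nb
          dkl_dlsig <- 0.5 * (1 - (pv[tb] + mres) / sig2)
          gv[tb] <- gv[tb] + dkl_dlsig * (lbeta[tb] - lpv[tb]) * w * (1 - w) / nb
        }
        gv <- hybrid_loss_weight * gv
        v_t <- v_t + 1L
        v_m <- 0.9 * v_m + 0.1 * gv
        v_v <- 0.999 * v_v + 0.001 * gv * gv
        v <- v - lr * (v_m / (1 - 0.9^v_t)) / (sqrt(v_v / (1 - 0.999^v_t)) + 1e-8)
        lossv <- lossv + hybrid_loss_weight * klsum
      }
      hist[s] <- lossv
    }
  })
  w <- 1 / (1 + exp(-v))
  beta_tilde <- exp(w * lbeta + (1 - w) * lpv)
  structure(list(net = net, schedule = schedule, beta_tilde = beta_tilde,
                 hybrid_loss_weight = hybrid_loss_weight,
                 loss_history = hist, seed = seed), class = "ddpm_model")
}

ddpm_eps_fn <- function(model) {
  function(yt, x, t) {
    vhat <- array(backbone_forward(model$net, abind_ch(yt, x), t = t), dim(yt))
    ab <- array(rep(model$schedule$alpha_bar[t], each = dim(yt)[1] * dim(yt)[2]),
                dim(yt))
    sqrt(ab) * vhat + sqrt(1 - ab) * yt
  }
}

#' Ancestral sampling from a conditional DDPM
#'
#' Runs the reverse chain
#' `y_{t-1} = (y_t - ((1-alpha_t)/sqrt(1-alpha_bar_t)) eta(y_t, x, t)) /
#' sqrt(alpha_t) + sqrt(beta_tilde(t)) eps` from `y_T ~ N(0, I)` down to
#' t = 1, with no noise added at the final step.
#'
#' @param model a `ddpm_model`, or an `eps_fn(y, x, t) -> array` for oracle
#'   chains (then `schedule` is required, inputs are taken as-is and no
#'   [0, 1] mapping or clipping is applied).
#' @param input_volume a [volume()] or (S, H, W) array.
#' @param n number of samples.
#' @param schedule required for oracle functions.
#' @param beta_tilde reverse variances; defaults to the model's learned ones
#'   (oracle default: 0, the noiseless reverse chain).
#' @param seed RNG seed.
#' @param max_batch largest slice batch per forward pass.
#' @return an `mrt_ensemble`.
#' @export
ddpm_sample <- function(model, input_volume, n = 20L, schedule = NULL,
                        beta_tilde = NULL, seed = 1L, max_batch = 64L) {
  stop_if_not(n >= 1, "n must be >= 1")
  oracle <- is.function(model)
  sched <- if (oracle) schedule else model$schedule
  stop_if_not(!is.null(sched), "schedule required for oracle eps functions")
  if (is.null(beta_tilde)) {
    beta_tilde <- if (oracle) rep(0, sched$T) else model$beta_tilde
  }
  if (length(beta_tilde) == 1L) beta_tilde <- rep(beta_tilde, sched$T)
  eps_fn <- if (oracle) model else ddpm_eps_fn(model)
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
      y <- array(stats::rnorm(H * W * nb), c(H, W, nb))
      for (t in seq.int(sched$T, 1L)) {
        pred <- eps_fn(y, xb, rep(t, nb))
        y <- (y - ((1 - sched$alpha[t]) / sqrt(1 - sched$alpha_bar[t])) * pred) /
          sqrt(sched$alpha[t])
        if (t > 1L && beta_tilde[t] > 0) {
          y <- y + sqrt(beta_tilde[t]) * array(stats::rnorm(length(y)), dim(y))
        }
      }
      res[, , st:en] <- y
    }
  })
  if (!oracle) res <- clip01((res + 1) / 2)
  samples_to_ensemble(res, S, n, model_tag = "ddpm",
                      input_ref = if (inherits(input_volume, "volume")) input_volume$subject_id else "")
}

#' Repair isolated outlier pixels in a DDPM ensemble mean
#'
#' DDPM chains occasionally leave isolated hyper/hypo-intense pixels. These
#' show up as outliers in the pixel-wise standard-deviation image: a pixel is
#' flagged when its std exceeds `median(std) + k * MAD(std)` computed within
#' the mask, and the mean image is repaired there with the pixel-wise median,
#' which is robust to the single aberrant sample. Idempotent (flags depend
#' only on the untouched std image).
#'
#' @param ens an `mrt_ensemble` with n >= 3.
#' @param mask logical array matching the volume shape (`NULL`: all voxels).
#' @param k robust threshold multiplier.
#' @return the ensemble with repaired `$mean` and a logical `$repaired`
#'   flag array.
#' @export
repair_outliers <- function(ens, mask = NULL, k = 5) {
  stop_if_not(inherits(ens, "mrt_ensemble"), "ens must be an mrt_ensemble")
  if (ens$n < 3L) stop("outlier repair needs n >= 3 samples", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim(ens$std))
  sv <- ens$std[mask]
  med <- stats::median(sv)
  madv <- stats::median(abs(sv - med))
  thr <- med + k * madv
  flag <- ens$std > thr & mask
  ens$mean[flag] <- ens$median[flag]
  ens$repaired <- flag
  ens
}
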