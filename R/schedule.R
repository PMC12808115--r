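#' Noise-variance schedules shared by the diffusion models
#'
#' Builds the per-step variances `beta[t]` (sigma_t^2) for `t = 1..T`.
#' `ncsn_geometric` is the variance-exploding schedule: a geometric sequence
#' from `beta_min` (the smallest, at t = 1) to `beta_max`; the score-network
#' lineage sets `sqrt(beta_max)` near the maximal pairwise distance between
#' training images. `ddpm_linear` is the variance-preserving schedule:
#' `beta[t]` linear in t with `0 < beta[1] < ... < beta[T] < 1` and derived
#' `alpha[t] = 1 - beta[t]`, `alpha_bar[t] = prod(alpha[1:t])`. The linear
#' endpoints follow the 1e-4..0.02 convention defined at T = 1000 and are
#' rescaled by 1000/T at smaller T so that `alpha_bar[T]` stays ~ exp(-10)
#' and the terminal marginal is close to N(0, I).
#'
#' @param kind `"ncsn_geometric"` or `"ddpm_linear"`.
#' @param T number of steps.
#' @param beta_min,beta_max endpoints for the geometric schedule.
#' @param beta_start,beta_end endpoints for the linear schedule at T = 1000
#'   (rescaled internally for other T).
#' @return a `noise_schedule` with fields `kind`, `T`, `beta`, and for DDPM
#'   also `alpha`, `alpha_bar`.
#' @export
noise_schedule <- function(kind = c("ncsn_geometric", "ddpm_linear"), T = 100L,
                           beta_min = 1e-4, beta_max = 25,
                           beta_start = 1e-4, beta_end = 0.02) {
  kind <- match.arg(kind)
  T <- as.integer(T)
  stop_if_not(T >= 1L, "T must be >= 1")
  if (kind == "ncsn_geometric") {
    stop_if_not(beta_min > 0 && beta_max > beta_min, "need 0 < beta_min < beta_max")
    beta <- exp(seq(log(beta_min), log(beta_max), length.out = T))
    if (T == 1L) beta <- beta_min
    sched <- list(kind = kind, T = T, beta = beta)
  } else {
    scale <- 1000 / T
    b1 <- beta_start * scale
    bT <- min(beta_end * scale, 0.999)
    beta <- seq(b1, bT, length.out = T)
    if (T == 1L) beta <- bT
    stop_if_not(all(beta > 0 & beta < 1), "DDPM betas must lie in (0, 1)")
    alpha <- 1 - beta
    sched <- list(kind = kind, T = T, beta = beta, alpha = alpha,
                  alpha_bar = cumprod(alpha))
  }
  structure(sched, class = "noise_schedule")
}

#' Annealed Langevin sampler settings
#'
#' Step sizes follow `gamma[t] = lambda_gamma * beta[t] / beta[1]`. Stability
#' with a well-trained score requires `lambda_gamma < 2 * beta[1]`; the
#' default `lambda_gamma = beta[1] * r / 2`, with `r = beta[t-1]/beta[t]` the
#' geometric ratio, makes the chain's noise level after the step at level t
#' equal the training noise level at t - 1, so the score model is always
#' evaluated at the noise scale it was trained on.
#'
#' @param schedule an `ncsn_geometric` [noise_schedule()].
#' @param lambda_gamma step-size scale; `NULL` for the matched default.
#' @return a `langevin_config` with `lambda_gamma` and step sizes `gamma`.
#' @export
langevin_config <- function(schedule, lambda_gamma = NULL) {
  stop_if_not(inherits(schedule, "noise_schedule"), "schedule required")
  if (is.null(lambda_gamma)) {
    r <- if (schedule$T > 1) schedule$beta[1] / schedule$beta[2] else 1
    lambda_gamma <- schedule$beta[1] * r / 2
  }
  if (lambda_gamma <= 0) stop("lambda_gamma must be > 0", call. = FALSE)
  gamma <- lambda_gamma * schedule$beta / schedule$beta[1]
  stop_if_not(all(gamma > 0), "step sizes must be positive")
  structure(list(lambda_gamma = lambda_gamma, gamma = gamma),
            class = "langevin_config")
}

# continuous-level extension of the geometric schedule: variance at a
# real-valued step index
sched_beta_at <- function(schedule, t) {
  stop_if_not(schedule$kind == "ncsn_geometric", "continuous levels need the geometric schedule")
  if (schedule$T == 1L) return(rep(schedule$beta[1], length(t)))
  lmin <- log(schedule$beta[1]); lmax <- log(schedule$beta[schedule$T])
  exp(lmin + (t - 1) / (schedule$T - 1) * (lmax - lmin))
}


check_t <- function(t, T) {
  if (any(t < 1) || any(t > T)) {
    stop("step index t out of range 1..", T, call. = FALSE)
  }
  as.integer(t)
}
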