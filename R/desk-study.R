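#' Reference desk-scale study protocol
#'
#' Runs the package's scaled-down end-to-end study on one CPU: a realistic
#' phantom cohort (32x32 slices, per-class intensity jitter, bias field,
#' noise) trains all four models; the exactly learnable noise-free rendering
#' of the same task provides the accuracy ceiling (masked volumetric SSIM of
#' the ensemble mean or point prediction); held-out in-distribution subjects
#' and zipper/low-SNR-corrupted subjects provide the sigma-hat OOD scores
#' for the probabilistic models. Problem sizes (10 training subjects of 4
#' slices, T = 100 diffusion steps, ensembles of n = 10, training budgets of
#' 25 epochs / 800 denoiser steps / 200 generator steps at 3 critic updates each) are the package's
#' desk-scale defaults, chosen so the full loop runs in minutes.
#'
#' @param seed master seed; every stage derives its RNG stream from it.
#' @param models subset of models to run.
#' @param n_id,n_ood_per_kind OOD-arm sizes (per corruption kind:
#'   `zipper` and `low_snr`).
#' @param n_samples ensemble size.
#' @param budget_scale multiplier on the training budgets (epochs / steps);
#'   values below 1 trade a little accuracy for wall-clock time.
#' @param verbose print stage timings.
#' @return list with per-model fits, similarity metrics on the noise-free
#'   subject, sigma-hat score sets, AUC / max-F1 per probabilistic model,
#'   coverage curves, and the DDPM repair count.
#' @export
desk_scale_study <- function(seed = 1L, models = c("direct", "cgan", "ncsn", "ddpm"),
                             n_id = 4L, n_ood_per_kind = 2L, n_samples = 10L,
                             budget_scale = 1, verbose = FALSE) {
  bs <- function(k) max(1L, as.integer(round(k * budget_scale)))
  t0 <- proc.time()
  say <- function(...) if (verbose) message(sprintf("[%7.1fs] ", (proc.time() - t0)[3]), ...)
  base <- as.integer(seed) * 1000L
  spec <- phantom_spec(image_size = 32L, n_slices = 4L, seed = base + 1L)
  cohort <- generate_cohort(spec, 10L)
  ds <- make_paired_dataset(cohort, "t1like", "t2like", c(0.8, 0, 0.2),
                            seed = base + 2L)
  # noise-free rendering of the separable task (8 slices: the volumetric
  # SSIM window needs >= 7)
  cspec <- phantom_spec(image_size = 32L, n_slices = 8L, noise_sd = 0,
                        intensity_jitter_sd = 0, bias_field_amplitude = 0,
                        seed = base + 3L)
  clean_subj <- generate_subject(cspec, base + 770L)
  target <- clean_subj$volumes$t2like
  # OOD arm: held-out realistic subjects, uncorrupted vs corrupted
  # (3 slices: the scalar score needs voxels, not a full SSIM-sized volume)
  ospec <- spec
  ospec$seed <- base + 4L
  ospec$n_slices <- 3L
  id_subjects <- generate_cohort(ospec, n_id)
  ood_subjects <- list()
  for (i in seq_len(n_ood_per_kind)) {
    s <- generate_subject(ospec, base + 800L + i)
    ood_subjects[[length(ood_subjects) + 1L]] <-
      corrupt(s, corruption_spec("zipper", severity = 2, seed = base + i))
    s2 <- generate_subject(ospec, base + 850L + i)
    ood_subjects[[length(ood_subjects) + 1L]] <-
      corrupt(s2, corruption_spec("low_snr", severity = 5, seed = base + i))
  }
  say("data ready")

  sched <- noise_schedule("ncsn_geometric", T = 100L, beta_min = 1e-4, beta_max = 1)
  fits <- list()
  metrics <- list()
  scores <- list()
  ood_stats <- list()
  coverage <- list()
  repaired_pixels <- NA_integer_

  eval_clean <- function(pred) {
    c(ssim = ssim3d(pred, target$data, mask = clean_subj$mask),
      psnr = psnr(pred, target$data),
      bssim = bssim(pred, target$data),
      scssim = scssim(pred, target$data))
  }
  score_set <- function(sample_fn, tag) {
    sid <- vapply(seq_along(id_subjects), function(k) {
      s <- id_subjects[[k]]
      sigma_hat(sample_fn(s, base + 300L + k), s$mask)
    }, numeric(1))
    sood <- vapply(seq_along(ood_subjects), function(k) {
      s <- ood_subjects[[k]]
      sigma_hat(sample_fn(s, base + 400L + k), s$mask)
    }, numeric(1))
    ood_scores(c(sprintf("id%02d", seq_along(sid)), sprintf("ood%02d", seq_along(sood))),
               c(sid, sood),
               c(rep("none", length(sid)),
                 vapply(ood_subjects, function(s) s$corruption$kind, "")),
               model_tag = tag)
  }

  for (m in models) {
    say("training ", m)
    if (m == "direct") {
      fit <- train_direct(ds$train, epochs = bs(25), batch_size = 8L, lr = 1e-3,
                          seed = base + 11L)
      pred <- infer_direct(fit, clean_subj$volumes$t1like)$data
      metrics[[m]] <- eval_clean(pred)
    } else if (m == "ncsn") {
      fit <- train_ncsn(ds$train, schedule = sched, steps = bs(800),
                        batch_size = 8L, lr = 1e-3, seed = base + 12L)
      say("sampling ncsn")
      ens <- ncsn_sample(fit, clean_subj$volumes$t1like, n = n_samples,
                         seed = base + 21L)
      metrics[[m]] <- eval_clean(ens$mean)
      coverage[[m]] <- coverage_curve(list(ens), list(target),
                                      masks = list(clean_subj$mask))
      scores[[m]] <- score_set(function(s, sd_) {
        ncsn_sample(fit, s$volumes$t1like, n = n_samples, seed = sd_)
      }, m)
    } else if (m == "ddpm") {
      fit <- train_ddpm(ds$train, steps = bs(800), batch_size = 8L, lr = 1e-3,
                        seed = base + 13L)
      say("sampling ddpm")
      ens <- repair_outliers(ddpm_sample(fit, clean_subj$volumes$t1like,
                                         n = n_samples, seed = base + 22L),
                             clean_subj$mask)
      repaired_pixels <- sum(ens$repaired)
      metrics[[m]] <- eval_clean(ens$mean)
      coverage[[m]] <- coverage_curve(list(ens), list(target),
                                      masks = list(clean_subj$mask))
    } else if (m == "cgan") {
      fit <- train_cgan(ds$train, gen_steps = bs(200), critic_steps = 3L,
                        batch_size = 8L, lr = 1e-3, seed = base + 14L)
      ens <- sample_cgan(fit, clean_subj$volumes$t1like, n = n_samples,
                         seed = base + 23L)
      metrics[[m]] <- eval_clean(ens$mean)
      scores[[m]] <- score_set(function(s, sd_) {
        sample_cgan(fit, s$volumes$t1like, n = n_samples, seed = sd_)
      }, m)
    }
    fits[[m]] <- fit
    say(m, " done")
  }
  for (m in names(scores)) {
    sc <- scores[[m]]
    ood_stats[[m]] <- list(auc = roc_auc(sc)$auc, max_f1 = f1_sweep(sc)$max_f1)
  }
  list(fits = fits, metrics = metrics, scores = scores, ood = ood_stats,
       coverage = coverage, repaired_pixels = repaired_pixels,
       clean_subject = clean_subj, elapsed = (proc.time() - t0)[3])
}
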