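#' Configuration for an end-to-end phantom study
#'
#' @param phantom a [phantom_spec()].
#' @param input_contrast,target_contrast the transformation (distinct
#'   contrasts present in the phantom profiles).
#' @param models subset of `c("direct", "cgan", "ncsn", "ddpm")`.
#' @param n_samples ensemble size for the probabilistic models (20 in the
#'   full study design; scale down for desk runs).
#' @param n_train,n_val,n_test in-distribution subject counts.
#' @param n_ood_val,n_ood_test OOD subjects per corruption kind for the
#'   calibration (validation) and evaluation (test) sets.
#' @param ood_kinds corruption kinds used for the OOD arm.
#' @param ood_severity severity of the corruptions (scalar or named by kind).
#' @param train_opts named list of per-model argument lists forwarded to the
#'   trainers (e.g. `list(ncsn = list(steps = 500))`).
#' @param seed master seed; all stages derive their seeds from it.
#' @param out_dir optional output directory for CSV reports.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_spec(),
                              input_contrast = "t1like", target_contrast = "t2like",
                              models = c("direct", "cgan", "ncsn", "ddpm"),
                              n_samples = 20L, n_train = 12L, n_val = 4L, n_test = 4L,
                              n_ood_val = 1L, n_ood_test = 1L,
                              ood_kinds = c("zipper", "low_snr"),
                              ood_severity = c(zipper = 2, ghosting = 2, low_snr = 5,
                                               tumor = 2, lesion = 2),
                              train_opts = list(), seed = 1L, out_dir = NULL) {
  stop_if_not(n_samples >= 1, "n_samples must be >= 1")
  stop_if_not(input_contrast != target_contrast, "transformation contrasts must differ")
  stop_if_not(all(models %in% c("direct", "cgan", "ncsn", "ddpm")), "unknown model")
  structure(list(phantom = phantom, input_contrast = input_contrast,
                 target_contrast = target_contrast, models = models,
                 n_samples = as.integer(n_samples), n_train = as.integer(n_train),
                 n_val = as.integer(n_val), n_test = as.integer(n_test),
                 n_ood_val = as.integer(n_ood_val), n_ood_test = as.integer(n_ood_test),
                 ood_kinds = ood_kinds, ood_severity = ood_severity,
                 train_opts = train_opts, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

ds_from_subjects <- function(subjects, input, target, split) {
  ds <- make_paired_dataset(subjects, input, target, split_fractions = c(1, 0, 0),
                            seed = 1L)$train
  ds$split <- split
  ds
}

predict_ensemble <- function(model_tag, fit, subject, input_contrast, n, seed) {
  xv <- subject$volumes[[input_contrast]]
  switch(model_tag,
         cgan = sample_cgan(fit, xv, n = n, seed = seed),
         ncsn = ncsn_sample(fit, xv, n = n, seed = seed),
         ddpm = {
           ens <- ddpm_sample(fit, xv, n = n, seed = seed)
           if (n >= 3) repair_outliers(ens, mask = subject$mask) else ens
         },
         stop("no ensemble sampler for model ", model_tag))
}

#' Run the full phantom transformation study
#'
#' Generates an in-distribution cohort, trains the requested models on the
#' training split, samples ensembles for every test subject, computes the
#' similarity metrics against the target contrast, derives the scalar
#' uncertainty score for ID and corrupted inputs, calibrates it with isotonic
#' regression on the validation arm, and evaluates coverage curves. Fully
#' seeded: rerunning with the same config reproduces all numbers.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print stage progress.
#' @return list with `fits`, `metrics` (long data frame), `summary`,
#'   `ood` (per-model score sets, AUC/F1, calibration, reliability),
#'   `coverage` (per-model coverage curves), and `splits`.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  spec <- cfg$phantom
  n_id <- cfg$n_train + cfg$n_val + cfg$n_test
  say("generating cohort (", n_id, " ID subjects)")
  subjects <- generate_cohort(spec, n_id)
  ord <- with_seed(cfg$seed, sample(n_id))
  idx_train <- ord[seq_len(cfg$n_train)]
  idx_val <- ord[cfg$n_train + seq_len(cfg$n_val)]
  idx_test <- ord[cfg$n_train + cfg$n_val + seq_len(cfg$n_test)]
  train_ds <- ds_from_subjects(subjects[idx_train], cfg$input_contrast,
                               cfg$target_contrast, "train")
  val_ds <- if (cfg$n_val > 0) ds_from_subjects(subjects[idx_val], cfg$input_contrast,
                                                cfg$target_contrast, "val") else NULL
  # OOD arms: fresh subjects with disjoint seeds, corrupted per kind
  ood_spec <- spec
  ood_spec$seed <- spec$seed + 1L
  ood_val <- if (cfg$n_ood_val > 0)
    generate_cohort(ood_spec, 0L, cfg$n_ood_val, ood_kinds = cfg$ood_kinds,
                    severity = cfg$ood_severity) else list()
  ood_spec$seed <- spec$seed + 2L
  ood_test <- if (cfg$n_ood_test > 0)
    generate_cohort(ood_spec, 0L, cfg$n_ood_test, ood_kinds = cfg$ood_kinds,
                    severity = cfg$ood_severity) else list()

  fits <- list()
  metrics_rows <- list()
  ood_out <- list()
  coverage_out <- list()
  for (m in cfg$models) {
    say("training ", m)
    opts <- cfg$train_opts[[m]] %||% list()
    fit <- switch(m,
                  direct = do.call(train_direct, c(list(data = train_ds, val = val_ds,
                                                        seed = cfg$seed + 10L), opts)),
                  cgan = do.call(train_cgan, c(list(data = train_ds,
                                                    seed = cfg$seed + 20L), opts)),
                  ncsn = do.call(train_ncsn, c(list(data = train_ds,
                                                    seed = cfg$seed + 30L), opts)),
                  ddpm = do.call(train_ddpm, c(list(data = train_ds,
                                                    seed = cfg$seed + 40L), opts)))
    fits[[m]] <- fit
    say("evaluating ", m, " on ", length(idx_test), " test subjects")
    test_ens <- list(); test_targets <- list(); test_masks <- list()
    for (k in seq_along(idx_test)) {
      s <- subjects[[idx_test[k]]]
      target <- s$volumes[[cfg$target_contrast]]
      if (m == "direct") {
        pred_vol <- infer_direct(fit, s$volumes[[cfg$input_contrast]])$data
        ens <- NULL
      } else {
        ens <- predict_ensemble(m, fit, s, cfg$input_contrast, cfg$n_samples,
                                seed = cfg$seed + 100L + k)
        pred_vol <- ens$mean
        test_ens[[length(test_ens) + 1L]] <- ens
        test_targets[[length(test_targets) + 1L]] <- target
        test_masks[[length(test_masks) + 1L]] <- s$mask
      }
      vals <- c(ssim = ssim3d(pred_vol, target$data, mask = s$mask),
                psnr = psnr(pred_vol, target$data),
                lpips = lpips_distance(pred_vol, target$data),
                bssim = bssim(pred_vol, target$data),
                scssim = scssim(pred_vol, target$data))
      metrics_rows[[length(metrics_rows) + 1L]] <-
        data.frame(subject_id = s$subject_id, model_tag = m,
                   metric = names(vals), value = as.numeric(vals),
                   stringsAsFactors = FALSE)
    }
    if (m != "direct") {
      coverage_out[[m]] <- coverage_curve(test_ens, test_targets, masks = test_masks)
      say("OOD scoring for ", m)
      score_subjects <- function(subs, tag) {
        if (length(subs) == 0) return(NULL)
        sc <- numeric(length(subs)); kind <- character(length(subs))
        for (k in seq_along(subs)) {
          s <- subs[[k]]
          ens <- predict_ensemble(m, fit, s, cfg$input_contrast, cfg$n_samples,
                                  seed = cfg$seed + 500L + k)
          sc[k] <- sigma_hat(ens, s$mask)
          kind[k] <- s$corruption$kind
        }
        ood_scores(vapply(subs, function(s) paste0(tag, "_", s$subject_id), ""),
                   sc, kind, model_tag = m)
      }
      val_sc <- rbind(score_subjects(subjects[idx_val], "val"),
                      score_subjects(ood_val, "oodval"))
      test_sc <- rbind(score_subjects(subjects[idx_test], "test"),
                       score_subjects(ood_test, "oodtest"))
      entry <- list(val = val_sc, test = test_sc)
      if (!is.null(test_sc) && length(unique(test_sc$label)) == 2) {
        entry$roc <- roc_auc(test_sc)
        entry$f1 <- f1_sweep(test_sc)
        if (!is.null(val_sc) && length(unique(val_sc$label)) == 2) {
          n_folds <- min(5L, sum(val_sc$label == 0))
          cal <- calibrate_isotonic(val_sc, test_sc, n_folds = n_folds,
                                    ood_subset_seed = cfg$seed)
          entry$calibration <- cal
          raw <- test_sc
          rng <- range(val_sc$score)
          raw$prob <- pmin(pmax((raw$score - rng[1]) / max(rng[2] - rng[1], 1e-12), 0), 1)
          entry$reliability_raw <- reliability_metrics(raw)
          entry$reliability_calibrated <- reliability_metrics(cal$calibrated)
          entry$roc_calibrated <- roc_auc(
            within(cal$calibrated, score <- prob))
        }
      }
      ood_out[[m]] <- entry
    }
  }
  metrics <- do.call(rbind, metrics_rows)
  res <- list(config = cfg, fits = fits, metrics = metrics,
              ood = ood_out, coverage = coverage_out,
              splits = list(train = idx_train, val = idx_val, test = idx_test))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"), row.names = FALSE)
    for (m in names(ood_out)) {
      if (!is.null(ood_out[[m]]$test)) {
        write.csv(ood_out[[m]]$test,
                  file.path(cfg$out_dir, paste0("sigma_hat_", m, ".csv")),
                  row.names = FALSE)
      }
      if (!is.null(coverage_out[[m]])) {
        write.csv(coverage_out[[m]],
                  file.path(cfg$out_dir, paste0("coverage_", m, ".csv")),
                  row.names = FALSE)
      }
    }
  }
  res
}
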