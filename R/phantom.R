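#' Specification for synthetic paired-contrast brain phantoms
#'
#' The generator emulates co-registered multi-contrast axial brain volumes:
#' one tissue-label volume per subject (nested ellipses for brain, CSF-like
#' ventricles, white-matter-like interior and a few subcortical-like blobs,
#' with per-subject geometric variability and smooth slice-to-slice
#' modulation), rendered into each contrast through a per-class intensity
#' profile, then modulated by a smooth multiplicative bias field, corrupted by
#' additive Gaussian noise inside the brain, and min-max normalized to [0, 1].
#' Because every contrast is rendered from the same tissue map, the
#' cross-contrast mapping is deterministic up to jitter/bias/noise — with all
#' three at zero it is exactly learnable, which the model tests exploit.
#'
#' @param image_size pixels per side of each square slice (>= 16).
#' @param n_slices axial slices per subject (>= 1).
#' @param tissue_classes ordered class names; the first must be "background".
#' @param contrast_profiles named list: contrast name -> numeric vector of
#'   per-class mean intensities in [0, 1] (background must map to 0).
#' @param intensity_jitter_sd per-subject, per-class Gaussian jitter SD.
#' @param bias_field_amplitude amplitude of the log-bias polynomial surface
#'   (the multiplicative field is `exp(amplitude * p(r))` with `|p| <= 1`).
#' @param noise_sd additive Gaussian noise SD (applied within the brain mask).
#' @param geometry_jitter fractional perturbation of structure shapes.
#' @param seed base RNG seed; identical spec + seeds give bit-identical data.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(image_size = 32L, n_slices = 8L,
                         tissue_classes = c("background", "csf", "gray", "white", "subcortical"),
                         contrast_profiles = list(
                           t1like = c(background = 0, csf = 0.15, gray = 0.45,
                                      white = 0.75, subcortical = 0.55),
                           t2like = c(background = 0, csf = 0.95, gray = 0.55,
                                      white = 0.30, subcortical = 0.45)),
                         intensity_jitter_sd = 0.02,
                         bias_field_amplitude = 0.05,
                         noise_sd = 0.02,
                         geometry_jitter = 0.05,
                         seed = 1L) {
  if (image_size < 16L || n_slices < 1L) {
    stop("invalid phantom spec: image_size must be >= 16 and n_slices >= 1",
         call. = FALSE)
  }
  stop_if_not(tissue_classes[1] == "background", "first tissue class must be background")
  for (nm in names(contrast_profiles)) {
    pr <- contrast_profiles[[nm]]
    stop_if_not(length(pr) == length(tissue_classes),
                "each contrast profile needs one mean per tissue class")
    stop_if_not(pr[[1]] == 0, "contrast profiles must assign background mean 0")
    stop_if_not(all(pr >= 0 & pr <= 1), "per-class means must lie in [0, 1]")
  }
  stop_if_not(intensity_jitter_sd >= 0 && bias_field_amplitude >= 0 &&
                noise_sd >= 0 && geometry_jitter >= 0,
              "jitter, noise and bias amplitudes must be >= 0")
  structure(list(image_size = as.integer(image_size), n_slices = as.integer(n_slices),
                 tissue_classes = tissue_classes, contrast_profiles = contrast_profiles,
                 intensity_jitter_sd = intensity_jitter_sd,
                 bias_field_amplitude = bias_field_amplitude,
                 noise_sd = noise_sd, geometry_jitter = geometry_jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Specify an out-of-distribution corruption
#'
#' Corruption kinds mirror common MR failure modes: `zipper` (periodic bright
#' dashed lines from RF interference), `ghosting` (an attenuated shifted copy
#' of the object), `low_snr` (inflated additive noise), `tumor` (a single
#' hyperintense blob, hyperintense only in the designated target contrast and
#' isointense with white matter in the others), and `lesion` (several small
#' hyperintense white-matter foci). `none` is the identity.
#'
#' @param kind one of `"none"`, `"zipper"`, `"ghosting"`, `"low_snr"`,
#'   `"tumor"`, `"lesion"`.
#' @param severity dimensionless severity scale (>= 0).
#' @param seed RNG seed for corruption placement.
#' @param target_contrast contrast in which pathology is hyperintense.
#' @return a `corruption_spec` object.
#' @export
corruption_spec <- function(kind = "none", severity = 1, seed = 1L,
                            target_contrast = NULL) {
  kinds <- c("none", "zipper", "ghosting", "low_snr", "tumor", "lesion")
  if (!kind %in% kinds) {
    stop("unknown corruption kind: ", kind, call. = FALSE)
  }
  stop_if_not(severity >= 0, "severity must be >= 0")
  structure(list(kind = kind, severity = severity, seed = as.integer(seed),
                 target_contrast = target_contrast),
            class = "corruption_spec")
}

# elliptical mask on a slice grid; radii in pixels, center in pixels
ellipse_mask <- function(n, cx, cy, rx, ry, theta = 0) {
  xs <- matrix(rep(seq_len(n), n), n, n) - cx
  ys <- matrix(rep(seq_len(n), each = n), n, n) - cy
  ct <- cos(theta); st <- sin(theta)
  u <- xs * ct + ys * st
  v <- -xs * st + ys * ct
  (u / rx)^2 + (v / ry)^2 <= 1
}

# per-subject tissue-label volume: 0 background, then csf/gray/white/subcortical
phantom_tissue_map <- function(spec) {
  n <- spec$image_size
  ns <- spec$n_slices
  gj <- spec$geometry_jitter
  jit <- function(x) x * (1 + stats::runif(1, -gj, gj))
  cx <- n / 2 + stats::runif(1, -gj, gj) * n / 8
  cy <- n / 2 + stats::runif(1, -gj, gj) * n / 8
  rx0 <- jit(0.40 * n); ry0 <- jit(0.44 * n)
  # subcortical blobs: 2-4, mid-radius ring
  nblob <- sample(2:4, 1)
  blob_ang <- stats::runif(nblob, 0, 2 * pi)
  blob_rad <- stats::runif(nblob, 0.12, 0.22) * n
  blob_r <- stats::runif(nblob, 0.05, 0.08) * n
  # ventricles: two small ellipses flanking the midline
  vent_dx <- jit(0.09 * n); vent_ry <- jit(0.12 * n); vent_rx <- jit(0.045 * n)
  tm <- array(0L, c(ns, n, n))
  # slice-axis modulation: elliptical profile so geometry varies smoothly
  zc <- (ns + 1) / 2
  zr <- if (ns > 1) 0.75 * ns else 1
  for (s in seq_len(ns)) {
    f <- sqrt(pmax(0, 1 - ((s - zc) / zr)^2))
    rx <- rx0 * f; ry <- ry0 * f
    if (rx < 2 || ry < 2) next
    sl <- matrix(0L, n, n)
    brain <- ellipse_mask(n, cx, cy, rx, ry)
    sl[brain] <- 2L                                   # gray-like shell
    white <- ellipse_mask(n, cx, cy, 0.72 * rx, 0.72 * ry)
    sl[white] <- 3L
    for (b in seq_len(nblob)) {
      bm <- ellipse_mask(n, cx + blob_rad[b] * cos(blob_ang[b]) * f,
                         cy + blob_rad[b] * sin(blob_ang[b]) * f,
                         blob_r[b] * f, blob_r[b] * f)
      sl[bm & white] <- 4L
    }
    vl <- ellipse_mask(n, cx - vent_dx * f, cy, vent_rx * f, vent_ry * f)
    vr <- ellipse_mask(n, cx + vent_dx * f, cy, vent_rx * f, vent_ry * f)
    sl[(vl | vr) & brain] <- 1L
    tm[s, , ] <- sl
  }
  tm
}

# smooth multiplicative bias field: exp(amplitude * low-order 2D polynomial),
# the polynomial scaled to max |value| = 1 over the slice
phantom_bias_field <- function(n, amplitude) {
  if (amplitude == 0) return(matrix(1, n, n))
  u <- matrix(rep(seq_len(n), n), n, n) / n - 0.5
  v <- matrix(rep(seq_len(n), each = n), n, n) / n - 0.5
  cf <- stats::rnorm(6)
  p <- cf[1] * u + cf[2] * v + cf[3] * u * v + cf[4] * (u^2 - 1 / 12) +
    cf[5] * (v^2 - 1 / 12) + cf[6] * u^2 * v
  p <- p / max(abs(p))
  exp(amplitude * p)
}

render_contrast <- function(tm, means, bias, noise_sd, mask) {
  ns <- dim(tm)[1]
  vol <- array(means[tm + 1L], dim(tm))
  for (s in seq_len(ns)) vol[s, , ] <- vol[s, , ] * bias
  if (noise_sd > 0) {
    nz <- array(stats::rnorm(length(vol), sd = noise_sd), dim(vol))
    vol[mask] <- vol[mask] + nz[mask]
  }
  vol[!mask] <- 0
  pmax(vol, 0)
}

#' Generate one phantom subject
#'
#' Renders all contrasts in `spec$contrast_profiles` from a single tissue map,
#' applies per-subject intensity jitter, a shared smooth bias field, additive
#' in-mask noise, and min-max normalizes each volume.
#'
#' @param spec a [phantom_spec()].
#' @param subject_seed integer seed; output is a pure function of
#'   (spec, subject_seed).
#' @return a `phantom_subject`: list with `subject_id`, `tissue_map`
#'   (slice, row, col integer array), `volumes` (named list of [volume()]),
#'   `mask`, and `corruption`.
#' @export
generate_subject <- function(spec, subject_seed = 1L) {
  stop_if_not(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  with_seed(subject_seed, {
    tm <- phantom_tissue_map(spec)
    mask <- tm != 0L
    bias <- phantom_bias_field(spec$image_size, spec$bias_field_amplitude)
    nclass <- length(spec$tissue_classes)
    vols <- list()
    for (cn in names(spec$contrast_profiles)) {
      means <- as.numeric(spec$contrast_profiles[[cn]])
      if (spec$intensity_jitter_sd > 0) {
        means <- means + c(0, stats::rnorm(nclass - 1, sd = spec$intensity_jitter_sd))
        means <- pmin(pmax(means, 0), 1)
      }
      dat <- render_contrast(tm, means, bias, spec$noise_sd, mask)
      v <- volume(dat, mask = mask, contrast = cn,
                  subject_id = sprintf("sub%05d", subject_seed))
      vols[[cn]] <- minmax_normalize(v)
    }
    structure(list(subject_id = sprintf("sub%05d", subject_seed),
                   tissue_map = tm, volumes = vols, mask = mask,
                   corruption = corruption_spec("none")),
              class = "phantom_subject")
  })
}

# insert an ellipsoidal blob label into the tissue map, centered in white matter
insert_blob <- function(tm, rad_frac, min_area = 12L) {
  d <- dim(tm)
  n <- d[2]
  white_idx <- which(tm == 3L, arr.ind = TRUE)
  mid <- white_idx[abs(white_idx[, 1] - (d[1] + 1) / 2) <= max(1, d[1] / 4), , drop = FALSE]
  if (nrow(mid) == 0) mid <- white_idx
  ctr <- mid[sample(nrow(mid), 1), ]
  r <- max(2.5, rad_frac * n)
  blob <- array(FALSE, d)
  zr <- max(1, d[1] / 3)
  for (s in seq_len(d[1])) {
    f <- sqrt(max(0, 1 - ((s - ctr[1]) / zr)^2))
    if (f <= 0) next
    em <- ellipse_mask(n, ctr[3], ctr[2], r * f, r * f)
    blob[s, , ] <- t(em) & tm[s, , ] != 0L
  }
  # grow the radius if the central cross-section is below the minimum area
  while (sum(blob[ctr[1], , ]) < min_area) {
    r <- r + 1
    em <- ellipse_mask(n, ctr[3], ctr[2], r, r)
    blob[ctr[1], , ] <- t(em) & tm[ctr[1], , ] != 0L
  }
  blob
}

#' Apply an out-of-distribution corruption to a phantom subject
#'
#' Artifact corruptions (`zipper`, `ghosting`, `low_snr`) act on the rendered
#' intensities of every contrast; pathology corruptions (`tumor`, `lesion`)
#' modify the tissue map and render hyperintense signal only in the designated
#' target contrast, staying isointense with white matter elsewhere (so a model
#' trained on clean anatomy cannot infer them from its input). Outputs are
#' clipped back into [0, 1] and the corruption is recorded in the subject.
#'
#' @param subject an uncorrupted `phantom_subject`.
#' @param c a [corruption_spec()].
#' @return the corrupted `phantom_subject`.
#' @export
corrupt <- function(subject, c) {
  stop_if_not(inherits(subject, "phantom_subject"), "subject must be a phantom_subject")
  stop_if_not(inherits(c, "corruption_spec"), "c must be a corruption_spec")
  stop_if_not(subject$corruption$kind == "none", "subject is already corrupted")
  if (c$kind == "none") return(subject)
  out <- subject
  out$corruption <- c
  with_seed(c$seed, {
    d <- dim(subject$mask)
    if (c$kind %in% c("zipper", "ghosting", "low_snr")) {
      for (cn in names(out$volumes)) {
        v <- out$volumes[[cn]]
        dat <- v$data
        if (c$kind == "zipper") {
          period <- max(4L, d[3] %/% 8L)
          phase <- sample(period, 1)
          cols <- seq.int(phase, d[3], by = period)
          dash <- (seq_len(d[2]) %% 8L) < 4L   # dashed: 4 on / 4 off
          amp <- 0.25 * c$severity
          for (cc in cols) dat[, dash, cc] <- dat[, dash, cc] + amp
        } else if (c$kind == "ghosting") {
          shift <- max(2L, d[3] %/% 4L)
          ghost <- dat[, , c((shift + 1):d[3], 1:shift), drop = FALSE]
          dat <- dat + 0.15 * c$severity * ghost
        } else {
          extra <- array(stats::rnorm(length(dat), sd = 0.02 * c$severity), d)
          dat[subject$mask] <- dat[subject$mask] + extra[subject$mask]
        }
        # inputs are already min-max normalized; clip the corrupted signal
        # back into [0, 1] (a full rescale would dim the uncorrupted tissue
        # and mask the artifact's intensity signature)
        v$data <- clip01(dat)
        out$volumes[[cn]] <- v
      }
    } else {
      target <- c$target_contrast %||% names(out$volumes)[length(out$volumes)]
      stop_if_not(target %in% names(out$volumes), "target_contrast not rendered")
      blob <- if (c$kind == "tumor") {
        insert_blob(out$tissue_map, rad_frac = 0.06 * sqrt(c$severity))
      } else {
        les <- array(FALSE, d)
        for (k in seq_len(3 + sample(3, 1))) les <- les | insert_blob(out$tissue_map, 0.018, min_area = 2L)
        les
      }
      out$tissue_map[blob] <- 5L
      for (cn in names(out$volumes)) {
        v <- out$volumes[[cn]]
        dat <- v$data
        if (cn == target) {
          dat[blob] <- 0.95          # hyperintense pathology in target contrast
        } else {
          white_med <- stats::median(dat[subject$tissue_map == 3L])
          dat[blob] <- white_med     # isointense with white matter in input
        }
        v$data <- clip01(dat)
        out$volumes[[cn]] <- v
      }
    }
  })
  out
}

#' Generate a cohort of phantom subjects with OOD variants
#'
#' @param spec a [phantom_spec()].
#' @param n_id number of uncorrupted (in-distribution) subjects.
#' @param n_ood_per_kind number of subjects per corruption kind (the five
#'   non-identity kinds).
#' @param ood_kinds corruption kinds to include.
#' @param severity severity per corruption: a single number, or a named
#'   vector keyed by kind. The defaults calibrate each artifact to the
#'   qualitative prominence of its real counterpart: zipper stripes at half
#'   the dynamic range, a ghost at 30 percent intensity, and low-SNR noise
#'   five times the nominal level (SNR ~ 5).
#' @return list of `phantom_subject`s; corrupted subjects carry their
#'   corruption spec (`$corruption$kind`) for later OOD labeling.
#' @export
generate_cohort <- function(spec, n_id, n_ood_per_kind = 0L,
                            ood_kinds = c("zipper", "ghosting", "low_snr", "tumor", "lesion"),
                            severity = c(zipper = 2, ghosting = 2, low_snr = 5,
                                         tumor = 2, lesion = 2)) {
  stop_if_not(n_id >= 0 && n_ood_per_kind >= 0, "counts must be >= 0")
  sev_of <- function(kind) {
    if (is.null(names(severity))) severity[1] else (severity[[kind]] %||% 2)
  }
  subjects <- list()
  sseed <- spec$seed * 10000L
  for (i in seq_len(n_id)) {
    subjects[[length(subjects) + 1L]] <- generate_subject(spec, sseed + i)
  }
  k <- n_id
  for (kind in if (n_ood_per_kind > 0) ood_kinds else character()) {
    for (i in seq_len(n_ood_per_kind)) {
      k <- k + 1L
      s <- generate_subject(spec, sseed + k)
      subjects[[length(subjects) + 1L]] <-
        corrupt(s, corruption_spec(kind, severity = sev_of(kind), seed = sseed + k))
    }
  }
  subjects
}
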