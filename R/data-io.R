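#' Single-contrast image volume
#'
#' The unit all metrics consume: a 3D intensity array laid out as
#' (slice, row, col) — axial slicing along the first axis — with an optional
#' binary brain mask of the same shape.
#'
#' @param data 3D numeric array (slice, row, col).
#' @param mask optional logical/0-1 array of the same shape.
#' @param contrast contrast name, e.g. `"t1like"`.
#' @param subject_id subject identifier.
#' @param normalized whether `data` is already min-max normalized.
#' @return a `volume` object.
#' @export
volume <- function(data, mask = NULL, contrast = "", subject_id = "",
                   normalized = FALSE) {
  stop_if_not(length(dim(data)) == 3, "data must be a 3D array")
  if (!is.null(mask)) {
    stop_if_not(all(dim(mask) == dim(data)), "mask shape must equal data shape")
    mask <- array(as.logical(mask), dim(mask))
  }
  structure(list(data = data, mask = mask, contrast = contrast,
                 subject_id = subject_id, normalized = isTRUE(normalized)),
            class = "volume")
}

#' Min-max normalize a volume to [0, 1]
#'
#' `(x - min) / (max - min)` over the full volume; a constant volume maps to
#' all zeros rather than dividing by zero. Idempotent.
#'
#' @param v a [volume()].
#' @return the normalized volume with `normalized = TRUE`.
#' @export
minmax_normalize <- function(v) {
  stop_if_not(inherits(v, "volume"), "v must be a volume")
  if (any(!is.finite(v$data))) stop("volume contains NaN/Inf", call. = FALSE)
  rng <- range(v$data)
  v$data <- if (rng[2] > rng[1]) (v$data - rng[1]) / (rng[2] - rng[1]) else array(0, dim(v$data))
  v$normalized <- TRUE
  v
}

#' Read / write volumes as NIfTI
#'
#' Volumes are written with an identity affine; the (slice, row, col) array is
#' stored as written, so a round-trip reproduces `v$data` to float precision.
#'
#' @param v a [volume()].
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @export
write_volume <- function(v, path) {
  stop_if_not(inherits(v, "volume"), "v must be a volume")
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop("unsupported volume format (expected .nii or .nii.gz): ", path, call. = FALSE)
  }
  RNifti::writeNifti(RNifti::asNifti(v$data), path)
  invisible(path)
}

#' @rdname write_volume
#' @param contrast,subject_id metadata attached to the volume read.
#' @return `read_volume()` returns a [volume()].
#' @export
read_volume <- function(path, contrast = "", subject_id = "") {
  if (!grepl("\\.nii(\\.gz)?$", path)) {
    stop("unsupported volume format (expected .nii or .nii.gz): ", path, call. = FALSE)
  }
  if (!file.exists(path)) stop("cannot read volume: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  volume(array(as.numeric(img), dim(img)), contrast = contrast, subject_id = subject_id)
}

#' Write a cohort to disk with a CSV manifest
#'
#' One NIfTI per subject/contrast plus the mask, and a manifest
#' (subject_id, contrast, path, corruption_kind) for reloading.
#'
#' @param subjects list of `phantom_subject`s.
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly; also written as
#'   `manifest.csv` in `dir`.
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in subjects) {
    for (cn in names(s$volumes)) {
      p <- file.path(dir, sprintf("%s_%s.nii.gz", s$subject_id, cn))
      write_volume(s$volumes[[cn]], p)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, contrast = cn, path = p,
        corruption_kind = s$corruption$kind, stringsAsFactors = FALSE)
    }
    mp <- file.path(dir, sprintf("%s_mask.nii.gz", s$subject_id))
    write_volume(volume(array(as.numeric(s$mask), dim(s$mask))), mp)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Build paired 2D slice datasets with a subject-level split
#'
#' Pairs up same-slice images of two contrasts across subjects and splits at
#' the subject level (a subject's slices never straddle splits) by a seeded
#' shuffle honoring the given fractions to rounding.
#'
#' @param subjects list of `phantom_subject`s.
#' @param input_contrast,target_contrast contrast names present in every
#'   subject.
#' @param split_fractions length-3 numeric (train, val, test) summing to 1.
#' @param seed shuffle seed.
#' @return named list of `paired_slice_dataset`s (`train`, `val`, `test`),
#'   each with arrays `x` and `y` of shape (H, W, n_pairs), plus
#'   `subject_id`, `slice_index` (0-based) and `split`.
#' @export
make_paired_dataset <- function(subjects, input_contrast, target_contrast,
                                split_fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stop_if_not(abs(sum(split_fractions) - 1) < 1e-8, "split fractions must sum to 1")
  for (s in subjects) {
    if (!all(c(input_contrast, target_contrast) %in% names(s$volumes))) {
      stop("subject ", s$subject_id, " is missing contrast ",
           paste(setdiff(c(input_contrast, target_contrast), names(s$volumes)),
                 collapse = ", "), call. = FALSE)
    }
  }
  ns <- length(subjects)
  ord <- with_seed(seed, sample(ns))
  n_train <- round(split_fractions[1] * ns)
  n_val <- round(split_fractions[2] * ns)
  idx <- list(train = ord[seq_len(n_train)],
              val = if (n_val > 0) ord[n_train + seq_len(n_val)] else integer(),
              test = if (ns > n_train + n_val) ord[(n_train + n_val + 1):ns] else integer())
  out <- list()
  for (sp in names(idx)) {
    xs <- list(); ys <- list(); sid <- character(); sli <- integer()
    for (i in idx[[sp]]) {
      s <- subjects[[i]]
      nv <- dim(s$volumes[[input_contrast]]$data)[1]
      for (k in seq_len(nv)) {
        xs[[length(xs) + 1L]] <- s$volumes[[input_contrast]]$data[k, , ]
        ys[[length(ys) + 1L]] <- s$volumes[[target_contrast]]$data[k, , ]
        sid <- c(sid, s$subject_id)
        sli <- c(sli, k - 1L)
      }
    }
    np <- length(xs)
    hw <- if (np > 0) dim(xs[[1]]) else c(0L, 0L)
    x <- array(0, c(hw, np)); y <- array(0, c(hw, np))
    for (k in seq_len(np)) { x[, , k] <- xs[[k]]; y[, , k] <- ys[[k]] }
    out[[sp]] <- structure(list(x = x, y = y, subject_id = sid,
                                slice_index = sli, slice_shape = hw, split = sp),
                           class = "paired_slice_dataset")
  }
  out
}

n_pairs <- function(ds) length(ds$subject_id)
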