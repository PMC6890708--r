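#' Phantom generator configuration
#'
#' Describes the synthetic brain phantom: a head ellipsoid filled with a
#' smooth random tissue texture plus voxelwise noise, and two planted
#' ellipsoidal disease-effect regions. AD-like scans receive a strong
#' localized intensity decrement (`delta_ad`, in units of the noise SD)
#' in the AD lesion; pMCI-like scans receive a subtler decrement
#' (`delta_mci`) in a partially overlapping region with a shifted centre,
#' so that AD-task features transfer to, but do not trivially solve, the
#' MCI-like task. NC and sMCI scans carry no effect.
#'
#' The default 24 x 32 x 24 grid keeps the 3:4:3 aspect of a
#' template-registered brain at 120 x 160 x 120 while remaining divisible
#' by 2 three times, so all three pooling stages of the networks stay
#' integral.
#'
#' @param grid_shape Integer length-3 grid shape.
#' @param head_center,head_radii Ellipsoid of "brain" tissue (1-based voxel
#'   coordinates / voxel units).
#' @param texture_scale Gaussian smoothing SD (voxels) of the tissue texture.
#' @param texture_amp Amplitude of the standardized texture field.
#' @param lesion_ad_center,lesion_ad_radii AD effect ellipsoid.
#' @param lesion_mci_center,lesion_mci_radii pMCI effect ellipsoid.
#' @param delta_ad,delta_mci Effect sizes in units of `noise_sd`.
#' @param noise_sd Additive voxel noise SD.
#' @return An object of class `vox_phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(24, 32, 24),
                           head_center = c(12.5, 16.5, 12.5),
                           head_radii = c(10, 14, 10),
                           texture_scale = 2,
                           texture_amp = 0.18,
                           lesion_ad_center = c(12.5, 20.5, 12.5),
                           lesion_ad_radii = c(3.5, 4.5, 3.5),
                           lesion_mci_center = c(11, 18.5, 12.5),
                           lesion_mci_radii = c(3.5, 4, 3.5),
                           delta_ad = 4,
                           delta_mci = 1.5,
                           noise_sd = 0.1) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape <= 0L)) stop("grid_shape must be positive")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (delta_ad < 0 || delta_mci < 0) stop("effect sizes must be >= 0")
  if (delta_mci > delta_ad)
    stop("delta_mci must not exceed delta_ad (the MCI effect is the subtler one)")
  cfg <- structure(list(grid_shape = grid_shape,
                        head_center = head_center, head_radii = head_radii,
                        texture_scale = texture_scale, texture_amp = texture_amp,
                        lesion_ad_center = lesion_ad_center,
                        lesion_ad_radii = lesion_ad_radii,
                        lesion_mci_center = lesion_mci_center,
                        lesion_mci_radii = lesion_mci_radii,
                        delta_ad = delta_ad, delta_mci = delta_mci,
                        noise_sd = noise_sd),
                   class = "vox_phantom_config")
  head <- ellipsoid_mask(grid_shape, head_center, head_radii)
  for (m in list(phantom_lesion_mask(cfg, "AD"), phantom_lesion_mask(cfg, "pMCI")))
    if (any(m & !head)) stop("lesion region must lie inside the head ellipsoid")
  cfg
}

ellipsoid_mask <- function(shape, center, radii) {
  i <- seq_len(shape[1]); j <- seq_len(shape[2]); k <- seq_len(shape[3])
  d2 <- outer(outer(((i - center[1]) / radii[1])^2,
                    ((j - center[2]) / radii[2])^2, `+`),
              ((k - center[3]) / radii[3])^2, `+`)
  d2 <= 1
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Ground-truth effect region of a phantom class
#'
#' @param config A [phantom_config()].
#' @param label Diagnostic label; NC and sMCI return an all-FALSE mask.
#' @return Logical 3D array.
#' @export
phantom_lesion_mask <- function(config, label) {
  label <- match.arg(label, VOX_LABELS)
  switch(label,
         AD = ellipsoid_mask(config$grid_shape, config$lesion_ad_center,
                             config$lesion_ad_radii),
         pMCI = ellipsoid_mask(config$grid_shape, config$lesion_mci_center,
                               config$lesion_mci_radii),
         array(FALSE, dim = config$grid_shape))
}

#' Generate one labeled phantom scan
#'
#' Baseline tissue is a Gaussian-smoothed white-noise texture (standardized,
#' scaled by `texture_amp`) around a mean of 0.55 inside the head ellipsoid.
#' Diseased labels subtract `delta * noise_sd` inside their effect region,
#' voxelwise Gaussian noise is added inside the head, negative intensities
#' are truncated at 0 (MRI magnitudes are non-negative), everything outside
#' the head is 0, and the result is min-max normalized to [0, 1]. The
#' planted region is recorded in the scan's `lesion_mask`.
#'
#' @param config A [phantom_config()].
#' @param label One of `"AD"`, `"NC"`, `"pMCI"`, `"sMCI"`.
#' @param seed Integer seed; identical `(config, label, seed)` gives an
#'   identical scan. `NULL` draws from the current RNG stream.
#' @param subject_id Identifier stored in the scan.
#' @return A [vox_scan()].
#' @export
generate_scan <- function(config, label, seed = NULL,
                          subject_id = paste0("phantom-", label)) {
  stopifnot(inherits(config, "vox_phantom_config"))
  label <- match.arg(label, VOX_LABELS)
  run <- function() {
    shape <- config$grid_shape
    n <- prod(shape)
    head <- ellipsoid_mask(shape, config$head_center, config$head_radii)
    tex <- array(rnorm(n), dim = shape)
    tex <- sep_filter3(tex, gaussian_kernel_1d(config$texture_scale))
    tex <- (tex - mean(tex)) / sd(tex)
    base <- 0.55 + config$texture_amp * tex
    lesion <- phantom_lesion_mask(config, label)
    delta <- switch(label, AD = config$delta_ad, pMCI = config$delta_mci, 0)
    base[lesion] <- base[lesion] - delta * config$noise_sd
    base <- base + array(rnorm(n, sd = config$noise_sd), dim = shape)
    # intensities are physically non-negative; truncating also keeps the
    # normalization anchored at the background rather than the lesion floor
    base[base < 0] <- 0
    base[!head] <- 0
    v <- normalize_intensity(vox_volume(base, space = "phantom"))
    vox_scan(v, label, subject_id, lesion_mask = lesion)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a labeled phantom cohort
#'
#' @param config A [phantom_config()].
#' @param n_per_class Named integer vector of per-class counts, e.g.
#'   `c(AD = 10, NC = 10)`; omitted classes default to 0.
#' @param seed Integer seed for the whole cohort.
#' @param prefix Prefix for generated subject ids.
#' @return List of [vox_scan()] with unique subject ids.
#' @export
generate_cohort <- function(config, n_per_class, seed = 1, prefix = "sub") {
  stopifnot(inherits(config, "vox_phantom_config"))
  counts <- stats::setNames(integer(4), VOX_LABELS)
  if (is.null(names(n_per_class))) {
    counts[seq_along(n_per_class)] <- n_per_class
  } else {
    stopifnot(all(names(n_per_class) %in% VOX_LABELS))
    counts[names(n_per_class)] <- n_per_class
  }
  if (any(counts < 0)) stop("class counts must be >= 0")
  withr::with_seed(seed, {
    scans <- list()
    for (lab in VOX_LABELS) {
      for (i in seq_len(counts[[lab]])) {
        scans[[length(scans) + 1L]] <-
          generate_scan(config, lab,
                        subject_id = sprintf("%s-%s-%03d", prefix, lab, i))
      }
    }
    scans
  })
}

#' Closed-form oracle classifier on a mask statistic
#'
#' Predicts the diseased label if and only if the mean intensity inside
#' `mask` falls below `threshold`. Used as an analytic reference against
#' which trained networks and the occlusion analysis are validated.
#'
#' @param mask Logical 3D array (must select at least one voxel).
#' @param threshold Decision threshold on the mask mean.
#' @param labels Length-2 character: diseased label, then healthy label.
#' @return An object of class `vox_oracle` usable with [predict_label()].
#' @export
oracle_classifier <- function(mask, threshold, labels = c("AD", "NC")) {
  if (sum(mask) == 0) stop("oracle mask is empty")
  stopifnot(length(labels) == 2, all(labels %in% VOX_LABELS))
  structure(list(mask = mask, threshold = threshold, labels = labels),
            class = "vox_oracle")
}

#' Predict the class label of a single volume
#'
#' Generic over classifier types: trained networks ([fine_tune()]) and
#' the analytic [oracle_classifier()].
#'
#' @param model A classifier object.
#' @param v A [vox_volume()] or bare 3D array.
#' @param ... Unused.
#' @return A single label string.
#' @export
predict_label <- function(model, v, ...) UseMethod("predict_label")

#' @export
predict_label.vox_oracle <- function(model, v, ...) {
  d <- if (inherits(v, "vox_volume")) v$data else v
  if (!identical(dim(d), dim(model$mask))) stop("mask shape mismatch")
  if (mean(d[model$mask]) < model$threshold) model$labels[1] else model$labels[2]
}

#' Classify a scan with the mask-mean oracle
#'
#' @param scan A [vox_scan()].
#' @param mask,threshold,labels Passed to [oracle_classifier()].
#' @return Predicted label.
#' @export
oracle_classify <- function(scan, mask, threshold, labels = c("AD", "NC")) {
  predict_label(oracle_classifier(mask, threshold, labels), scan$volume)
}

#' Calibrate the oracle threshold at the midpoint of the class means
#'
#' Draws `n` fresh scans per class, computes the mean lesion-mask intensity
#' of each, and places the threshold halfway between the two class means.
#'
#' @param config A [phantom_config()].
#' @param labels Length-2: diseased, healthy.
#' @param n Calibration scans per class.
#' @param seed Seed for the calibration draws.
#' @return A calibrated [oracle_classifier()].
#' @export
calibrate_oracle <- function(config, labels = c("AD", "NC"), n = 50, seed = 1) {
  mask <- phantom_lesion_mask(config, labels[1])
  stat <- function(lab, s0)
    vapply(seq_len(n), function(i) {
      sc <- generate_scan(config, lab, seed = s0 + i)
      mean(sc$volume$data[mask])
    }, 0)
  m_dis <- mean(stat(labels[1], seed * 1000L))
  m_hea <- mean(stat(labels[2], seed * 1000L + n))
  oracle_classifier(mask, (m_dis + m_hea) / 2, labels)
}

#' Write a cohort to disk as NIfTI scans plus a manifest
#'
#' Writes one `.nii.gz` per scan, optional lesion masks, and a tab-delimited
#' `manifest.tsv` with columns `subject_id`, `path`, `label`.
#'
#' @param scans List of [vox_scan()].
#' @param dir Output directory (created if needed).
#' @param masks Also write `<id>_mask.nii.gz` files for scans with masks.
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(scans, dir, masks = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(scans, function(s) {
    f <- paste0(s$subject_id, ".nii.gz")
    write_volume(s$volume, file.path(dir, f))
    if (masks && !is.null(s$lesion_mask))
      write_volume(s$lesion_mask + 0, file.path(dir, paste0(s$subject_id, "_mask.nii.gz")))
    data.frame(subject_id = s$subject_id, path = f, label = s$label)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.tsv")
  write.table(manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mf)
}
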