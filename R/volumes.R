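#' Construct a volume object
#'
#' A `vox_volume` wraps a dense 3D intensity grid together with its voxel
#' spacing (mm per axis) and a free-text tag identifying the template grid
#' the volume lives on. All downstream operations (networks, saliency,
#' phantoms) consume and produce this class.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing Numeric length-3 voxel size in mm.
#' @param space Character tag for the reference grid.
#' @return An object of class `vox_volume`.
#' @export
vox_volume <- function(data, spacing = c(1, 1, 1), space = "unknown") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dimensions")
  if (any(dim(data) <= 0L)) stop("volume dimensions must be strictly positive")
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  structure(list(data = data, spacing = as.numeric(spacing), space = space),
            class = "vox_volume")
}

#' @export
print.vox_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vox_volume> %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.vox_volume <- function(x) dim(x$data)

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @return A [vox_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), " dimensions (", path, ")")
  vox_volume(array(as.numeric(img), dim = d),
             spacing = RNifti::pixdim(img)[seq_len(3)],
             space = path)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param v A [vox_volume()] or plain 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (inherits(v, "vox_volume")) {
    img <- RNifti::asNifti(v$data)
    RNifti::pixdim(img) <- v$spacing
  } else {
    img <- RNifti::asNifti(v)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Min-max intensity normalization to [0, 1]
#'
#' Rescales intensities so the minimum maps to 0 and the maximum to 1.
#' A constant-valued volume maps to all zeros (the degenerate range would
#' otherwise divide by zero). The operation is idempotent.
#'
#' @param v A [vox_volume()].
#' @return A normalized [vox_volume()].
#' @export
normalize_intensity <- function(v) {
  stopifnot(inherits(v, "vox_volume"))
  d <- v$data
  if (!all(is.finite(d))) stop("volume contains non-finite values")
  lo <- min(d); hi <- max(d)
  v$data <- if (hi > lo) (d - lo) / (hi - lo) else array(0, dim = dim(d))
  v
}

#' Trilinear resampling onto a target grid
#'
#' Resamples a volume to `target_shape` by trilinear interpolation with the
#' grid corners of the source and target lattices aligned, so endpoint
#' values are preserved. Voxel spacing is rescaled to keep the physical
#' field of view.
#'
#' @param v A [vox_volume()].
#' @param target_shape Integer length-3 target grid shape.
#' @return A resampled [vox_volume()].
#' @export
resample <- function(v, target_shape) {
  stopifnot(inherits(v, "vox_volume"))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape <= 0L))
    stop("target_shape must be three positive integers")
  out <- resample_trilinear(v$data, target_shape)
  vox_volume(out, spacing = v$spacing * dim(v$data) / target_shape,
             space = v$space)
}

#' Data augmentation parameters
#'
#' Intervals from which the on-the-fly augmentation draws its random
#' transform: per-axis rotation (degrees), per-axis translation as a
#' fraction of the axis extent (a sign is drawn at random), isotropic
#' rescaling, additive brightness jitter and multiplicative contrast
#' jitter about the volume mean. MRI is single-channel, so hue-type
#' photometric jitter has no analogue here; intensity jitter is limited
#' to brightness and contrast.
#'
#' @param rotation_deg,shift_frac,scale,brightness,contrast Closed intervals
#'   (length-2 numeric, low then high).
#' @return An object of class `vox_augment_params`.
#' @export
augment_params <- function(rotation_deg = c(-5, 5),
                           shift_frac = c(0, 0.1),
                           scale = c(0.8, 1.2),
                           brightness = c(-0.1, 0.1),
                           contrast = c(0.9, 1.1)) {
  iv <- function(x, nm, positive = FALSE) {
    if (length(x) != 2L || x[1] > x[2]) stop(nm, " must be an ordered interval")
    if (positive && x[1] <= 0) stop(nm, " must be strictly positive")
    as.numeric(x)
  }
  structure(list(rotation_deg = iv(rotation_deg, "rotation_deg"),
                 shift_frac = iv(shift_frac, "shift_frac"),
                 scale = iv(scale, "scale", positive = TRUE),
                 brightness = iv(brightness, "brightness"),
                 contrast = iv(contrast, "contrast")),
            class = "vox_augment_params")
}

runif1 <- function(iv) if (iv[1] == iv[2]) iv[1] else runif(1, iv[1], iv[2])

# used where the argument name `augment_params` shadows the constructor
default_augment_params <- function() augment_params()

#' Randomly augment a volume
#'
#' Applies, in order: a rotation per axis about the volume centre, a
#' translation per axis, an isotropic rescale about the centre (all drawn
#' uniformly from the configured intervals), then brightness and contrast
#' jitter. Geometry is resampled trilinearly in a single pass; voxels
#' mapped from outside the field of view are filled with 0, and the result
#' is clipped back to [0, 1]. Given the same seed the output is identical.
#'
#' @param v A [vox_volume()] with intensities in [0, 1].
#' @param params An [augment_params()] object.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An augmented [vox_volume()] of the same shape.
#' @export
augment <- function(v, params = augment_params(), seed = NULL) {
  stopifnot(inherits(v, "vox_volume"), inherits(params, "vox_augment_params"))
  run <- function() {
    ang <- vapply(1:3, function(i) runif1(params$rotation_deg), 0) * pi / 180
    ext <- dim(v$data)
    shift <- vapply(1:3, function(i) runif1(params$shift_frac), 0) * ext *
      sample(c(-1, 1), 3, replace = TRUE)
    sc <- runif1(params$scale)
    bright <- runif1(params$brightness)
    contr <- runif1(params$contrast)
    rot <- function(a, i, j) {
      R <- diag(3)
      R[i, i] <- cos(a); R[j, j] <- cos(a)
      R[i, j] <- -sin(a); R[j, i] <- sin(a)
      R
    }
    R <- rot(ang[3], 1, 2) %*% rot(ang[2], 1, 3) %*% rot(ang[1], 2, 3)
    centre <- (ext - 1) / 2
    # forward transform y = sc * R (x - c) + c + shift; sample at its inverse
    Minv <- t(R) / sc
    off <- as.numeric(centre - Minv %*% (centre + shift))
    out <- affine_sample(v$data, Minv, off)
    m <- mean(out)
    out <- (out - m) * contr + m + bright
    out[out < 0] <- 0
    out[out > 1] <- 1
    vox_volume(out, spacing = v$spacing, space = v$space)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Construct a labeled scan
#'
#' Bundles a volume with its diagnostic label, a subject identifier and,
#' for phantom data, the ground-truth lesion mask of the planted effect.
#'
#' @param volume A [vox_volume()].
#' @param label One of `"AD"`, `"NC"`, `"pMCI"`, `"sMCI"`.
#' @param subject_id Opaque subject identifier.
#' @param lesion_mask Optional logical/0-1 array of the same shape.
#' @return An object of class `vox_scan`.
#' @export
vox_scan <- function(volume, label, subject_id, lesion_mask = NULL) {
  stopifnot(inherits(volume, "vox_volume"))
  label <- match.arg(label, VOX_LABELS)
  if (!is.null(lesion_mask)) {
    if (!identical(dim(lesion_mask), dim(volume$data)))
      stop("lesion_mask shape must match the volume")
    storage.mode(lesion_mask) <- "logical"
  }
  structure(list(volume = volume, label = label,
                 subject_id = as.character(subject_id),
                 lesion_mask = lesion_mask),
            class = "vox_scan")
}

#' @export
print.vox_scan <- function(x, ...) {
  cat(sprintf("<vox_scan> %s [%s], %s voxels%s\n", x$subject_id, x$label,
              paste(dim(x$volume$data), collapse = "x"),
              if (is.null(x$lesion_mask)) "" else
                sprintf(", lesion mask (%d voxels)", sum(x$lesion_mask))))
  invisible(x)
}

scan_labels <- function(scans) vapply(scans, function(s) s$label, "")
scan_ids <- function(scans) vapply(scans, function(s) s$subject_id, "")

#' Read a cohort manifest
#'
#' The manifest is a tab-delimited table with columns `subject_id`, `path`
#' and `label`; relative paths are resolved against the manifest location.
#'
#' @param path Manifest file path.
#' @return A data frame with the three columns.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Load the scans listed in a manifest
#'
#' @param manifest Path to a manifest file or a data frame from
#'   [read_manifest()].
#' @return A list of [vox_scan()] objects.
#' @export
read_cohort <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i)
    vox_scan(read_volume(manifest$path[i]), manifest$label[i],
             manifest$subject_id[i]))
}
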