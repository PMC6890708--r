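# Class saliency visualization (voxelwise |d f_c / d x| by backpropagation)
# and supervoxel occlusion sensitivity analysis.

#' Instance class saliency map
#'
#' First-order (Taylor) attribution of a classifier's class score: the
#' absolute partial derivative of the pre-softmax score of class `c` with
#' respect to each input voxel, computed by backpropagation in inference
#' mode. For an affine scorer `f_c(x) = w' x + b` the map is exactly `|w|`.
#' Differentiation at the logit rather than the softmax output avoids
#' saturated (vanishing) gradients.
#'
#' @param model A `vox_model` classifier.
#' @param v Input [vox_volume()] or 3D array matching the network grid.
#' @param class Target class label (one of the model's two labels).
#' @return An object of class `vox_saliency`: a non-negative 3D `grid`
#'   plus the class tag and provenance.
#' @export
instance_saliency <- function(model, v, class) {
  stopifnot(inherits(model, "vox_model"))
  ci <- match(class, model$labels)
  if (is.na(ci)) stop("unknown class '", class, "' for task ", model$task)
  fw <- net_forward(model$net, v)
  g <- numeric(length(fw$out))
  g[ci] <- 1
  bw <- net_backward(model$net, fw$cache, g)
  grid <- abs(array(bw$gx, dim = dim(bw$gx)[-1]))
  new_saliency(grid, class, "instance")
}

new_saliency <- function(grid, class, provenance) {
  structure(list(grid = grid, class = class, provenance = provenance),
            class = "vox_saliency")
}

#' @export
print.vox_saliency <- function(x, ...) {
  cat(sprintf("<vox_saliency> %s map for class %s, %s voxels, max %.4g\n",
              x$provenance, x$class, paste(dim(x$grid), collapse = "x"),
              max(x$grid)))
  invisible(x)
}

#' Smooth a saliency map
#'
#' Applies a cubic mean (box) filter of odd side `size` with reflecting
#' boundaries; a Gaussian filter of SD `size / 4` voxels is available as an
#' alternative. Non-negativity is preserved and, away from boundaries,
#' total mass is conserved by the box filter.
#'
#' @param m A `vox_saliency` or 3D array.
#' @param size Odd positive filter side length.
#' @param type `"box"` (default) or `"gaussian"`.
#' @return Smoothed object of the same kind.
#' @export
smooth_map <- function(m, size = 9L, type = c("box", "gaussian")) {
  type <- match.arg(type)
  size <- as.integer(size)
  if (size <= 0 || size %% 2L == 0L) stop("size must be odd and positive")
  grid <- if (inherits(m, "vox_saliency")) m$grid else m
  kern <- if (type == "box") rep(1 / size, size) else gaussian_kernel_1d(size / 4)
  sm <- sep_filter3(grid, kern)
  if (inherits(m, "vox_saliency")) {
    m$grid <- sm
    m
  } else sm
}

#' Group (class-level) saliency map
#'
#' Computes the instance saliency of every scan of the target class,
#' smooths each map, sums them voxelwise and min-max normalizes the result
#' to `[0, 1]` (maximum exactly 1 unless the summed map is constant).
#' Duplicating scans leaves the map unchanged.
#'
#' @param model A `vox_model` classifier.
#' @param scans Non-empty list of [vox_scan()], all labeled `class`.
#' @param class Target class.
#' @param smooth_size Side of the smoothing filter (see [smooth_map()]).
#' @return A `vox_saliency` with provenance `"group"`.
#' @export
group_saliency <- function(model, scans, class, smooth_size = 9L) {
  if (length(scans) == 0) stop("no scans supplied")
  labs <- scan_labels(scans)
  if (!all(labs == class))
    stop("all scans must carry the target class label '", class, "'")
  total <- NULL
  for (s in scans) {
    m <- smooth_map(instance_saliency(model, s$volume, class), smooth_size)
    total <- if (is.null(total)) m$grid else total + m$grid
  }
  lo <- min(total); hi <- max(total)
  grid <- if (hi > lo) (total - lo) / (hi - lo) else array(0, dim = dim(total))
  new_saliency(grid, class, "group")
}

#' SLIC-style supervoxel segmentation
#'
#' Partitions the grid into approximately `n_segments` spatially contiguous
#' clusters by iterative local k-means on (intensity, position), followed
#' by a connectivity pass that absorbs small fragments into an adjacent
#' segment. The achieved count can deviate from the request (typically
#' within about 20 percent).
#'
#' @param v A [vox_volume()] or 3D array.
#' @param n_segments Requested segment count (>= 1, at most the voxel count).
#' @param compactness Trade-off between intensity and spatial proximity;
#'   smaller values let segments follow intensity boundaries more closely.
#' @param max_iter Local k-means iterations.
#' @return Integer 3D array of labels `1..S`, class `vox_segmentation`.
#' @export
supervoxel_segment <- function(v, n_segments = 100L, compactness = 0.1,
                               max_iter = 10L) {
  d <- if (inherits(v, "vox_volume")) v$data else v
  n_segments <- as.integer(n_segments)
  if (n_segments < 1) stop("n_segments must be >= 1")
  if (n_segments > length(d)) stop("n_segments exceeds the voxel count")
  lab <- slic3d(d, n_segments, compactness, as.integer(max_iter), 0.25)
  class(lab) <- c("vox_segmentation", class(lab))
  lab
}

#' Supervoxel occlusion (shrinkage) simulation
#'
#' For every scan predicted as `from` and every supervoxel, sets the
#' supervoxel's voxels to 0, re-runs inference, and counts a "flip" for
#' that supervoxel when the prediction changes from `from` to `to`. Counts
#' accumulate over scans; the per-voxel grid carries its supervoxel's
#' count.
#'
#' @param model A classifier ([fine_tune()] model or [oracle_classifier()]).
#' @param scans List of [vox_scan()].
#' @param seg A segmentation from [supervoxel_segment()] (same grid).
#' @param from,to Source and target class of the decision flip.
#' @return An object of class `vox_importance`: `counts` (per supervoxel),
#'   `grid` (per voxel), `n_scans` (scans actually tested).
#' @export
occlusion_simulation <- function(model, scans, seg, from, to) {
  d0 <- if (inherits(scans[[1]], "vox_scan")) dim(scans[[1]]$volume$data)
        else dim(scans[[1]])
  if (!identical(dim(seg), d0)) stop("segmentation shape mismatch")
  nseg <- max(seg)
  counts <- integer(nseg)
  tested <- 0L
  voxel_sets <- lapply(seq_len(nseg), function(s) which(seg == s))
  for (s in scans) {
    v <- if (inherits(s, "vox_scan")) s$volume$data else s
    if (predict_label(model, v) != from) next
    tested <- tested + 1L
    for (k in seq_len(nseg)) {
      v2 <- v
      v2[voxel_sets[[k]]] <- 0
      if (predict_label(model, v2) == to) counts[k] <- counts[k] + 1L
    }
  }
  grid <- array(counts[seg], dim = dim(seg))
  structure(list(counts = counts, grid = grid, n_scans = tested,
                 from = from, to = to),
            class = "vox_importance")
}

#' @export
print.vox_importance <- function(x, ...) {
  cat(sprintf("<vox_importance> %s -> %s flips over %d scans, %d supervoxels, max count %d\n",
              x$from, x$to, x$n_scans, length(x$counts), max(x$counts)))
  invisible(x)
}

#' Threshold a map at a fraction of its maximum
#'
#' Returns the binary region of interest containing every voxel with value
#' at least `fraction` times the global maximum. An all-zero map yields an
#' empty mask.
#'
#' @param m A `vox_saliency`, `vox_importance` or 3D array.
#' @param fraction Threshold fraction in (0, 1]; default 0.8.
#' @return Logical 3D array.
#' @export
threshold_roi <- function(m, fraction = 0.8) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  grid <- if (inherits(m, "vox_saliency")) m$grid
          else if (inherits(m, "vox_importance")) m$grid
          else m
  mx <- max(grid)
  if (mx <= 0) return(array(FALSE, dim = dim(grid)))
  grid >= fraction * mx
}

#' Write a saliency or importance map as NIfTI
#'
#' @param m A `vox_saliency` or `vox_importance`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @param spacing Voxel spacing to record.
#' @return `path`, invisibly.
#' @export
write_map <- function(m, path, spacing = c(1, 1, 1)) {
  grid <- if (inherits(m, "vox_saliency")) m$grid else m$grid
  write_volume(vox_volume(grid * 1, spacing = spacing, space = "map"), path)
}
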