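#' Resample a volume or label map to a target spacing
#'
#' Output grid dimensions are `round(dim * spacing / target_spacing)`;
#' voxel values are interpolated trilinearly for images and by nearest
#' neighbour for label maps (nearest is mandatory for labels).  The default
#' preprocessing recipe for the prostate task resamples to
#' 0.5 x 0.5 x 3.0 mm, the pancreas recipe to 1.0 x 1.0 x 3.0 mm.
#'
#' @param x a [volume()] or [label_map()].
#' @param target_spacing numeric length-3 spacing in mm, all > 0.
#' @param mode `"linear"` or `"nearest"`; label maps must use `"nearest"`.
#' @return an object of the same type as `x` on the resampled grid.
#' @export
resample <- function(x, target_spacing,
                     mode = if (is_labelmap(x)) "nearest" else "linear") {
  mode <- match.arg(mode, c("linear", "nearest"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0)) {
    abort("`target_spacing` must be three positive numbers.", class = "segda_usage_error")
  }
  if (is_labelmap(x) && mode == "linear") {
    abort("label maps must be resampled with mode = \"nearest\".",
          class = "segda_usage_error")
  }
  in_dim <- dim(x$data)
  out_dim <- pmax(1L, as.integer(round(in_dim * x$spacing / target_spacing)))
  scale <- target_spacing / x$spacing
  out <- cpp_affine_sample3d(as.numeric(x$data), in_dim, out_dim,
                             scale, c(0, 0, 0),
                             mode = if (mode == "linear") 0L else 1L,
                             border = 1L, fill = 0)
  if (is_labelmap(x)) {
    label_map(array(as.integer(round(out)), out_dim),
              spacing = target_spacing, origin = x$origin, n_classes = x$n_classes)
  } else {
    volume(array(out, out_dim), spacing = target_spacing, origin = x$origin)
  }
}

# Extract a window [start, start + size) with symmetric zero/background
# padding where the window leaves the grid.  `start` is 0-based.
extract_window <- function(x, start, size, pad_value = 0) {
  in_dim <- dim(x$data)
  out <- array(pad_value, size)
  src_lo <- pmax(start, 0L)
  src_hi <- pmin(start + size, in_dim)
  if (all(src_hi > src_lo)) {
    dst_lo <- src_lo - start
    out[(dst_lo[1] + 1):(dst_lo[1] + src_hi[1] - src_lo[1]),
        (dst_lo[2] + 1):(dst_lo[2] + src_hi[2] - src_lo[2]),
        (dst_lo[3] + 1):(dst_lo[3] + src_hi[3] - src_lo[3])] <-
      x$data[(src_lo[1] + 1):src_hi[1],
             (src_lo[2] + 1):src_hi[2],
             (src_lo[3] + 1):src_hi[3]]
  }
  origin <- x$origin + start * x$spacing
  if (is_labelmap(x)) {
    label_map(array(as.integer(out), size), x$spacing, origin, x$n_classes)
  } else {
    volume(out, x$spacing, origin)
  }
}

#' Crop (or pad) to a fixed size around the grid center
#'
#' Extracts a centred window of `size` voxels; axes where the input is
#' smaller than `size` are padded symmetrically with zeros (background for
#' label maps).  The prostate recipe crops to 184 x 184 x 32 after
#' resampling; the pancreas recipe to a 200 x 128 x 48 region of interest.
#'
#' @param x a [volume()] or [label_map()].
#' @param size integer length-3 target dimensions.
#' @return same type as `x` with `dim(x) == size`.
#' @export
crop_center <- function(x, size) {
  size <- as.integer(size)
  if (length(size) != 3L || any(size <= 0)) {
    abort("`size` must be three positive integers.", class = "segda_usage_error")
  }
  start <- as.integer(floor((dim(x$data) - size) / 2))
  extract_window(x, start, size)
}

#' Crop to a region of interest centred on a reference segmentation
#'
#' Implements ROI extraction around a ground-truth structure: the window is
#' centred on the centre of the foreground bounding box of `reference` and
#' padded where it leaves the grid.
#'
#' @param x a [volume()] or [label_map()] to crop.
#' @param reference a [label_map()] whose foreground (label > 0) defines the ROI.
#' @param size integer length-3 window size.
#' @return same type as `x`.
#' @export
crop_roi <- function(x, reference, size) {
  stopifnot(is_labelmap(reference))
  size <- as.integer(size)
  idx <- which(reference$data > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(crop_center(x, size))
  center <- (apply(idx, 2, min) + apply(idx, 2, max)) / 2 - 1  # 0-based
  start <- as.integer(round(center - (size - 1) / 2))
  extract_window(x, start, size)
}

#' Intensity normalization recipes
#'
#' Two schemes, matching the MRI and CT preprocessing recipes:
#' \describe{
#'   \item{`mri_percentile`}{per-volume clipping to the 1st and 99th
#'     intensity percentile, then linear rescaling of the clipped range to
#'     `[0, 1]`.}
#'   \item{`ct_window`}{clipping to the Hounsfield window `[-300, 300]`,
#'     then standardization to zero mean and unit variance.}
#' }
#' A constant (degenerate) volume maps to all zeros under both schemes.
#'
#' @param vol a [volume()].
#' @param scheme `"mri_percentile"` or `"ct_window"`.
#' @param window CT clipping window (only used by `ct_window`).
#' @param probs clip percentiles (only used by `mri_percentile`).
#' @return a normalized [volume()].
#' @export
normalize <- function(vol, scheme = c("mri_percentile", "ct_window"),
                      window = c(-300, 300), probs = c(0.01, 0.99)) {
  stopifnot(is_volume(vol))
  scheme <- match.arg(scheme)
  x <- vol$data
  if (scheme == "mri_percentile") {
    q <- quantile(x, probs = probs, names = FALSE)
    x <- pmin(pmax(x, q[1]), q[2])
    if (q[2] > q[1]) x <- (x - q[1]) / (q[2] - q[1]) else x[] <- 0
  } else {
    x <- pmin(pmax(x, window[1]), window[2])
    s <- sd(x)
    if (s > 0) x <- (x - mean(x)) / s else x[] <- 0
  }
  volume(array(x, dim(vol$data)), vol$spacing, vol$origin)
}

#' Data augmentation recipes
#'
#' Applies one of the two training-time augmentation schemes to an
#' image/label pair.  Geometric transforms are applied identically to both
#' (labels via nearest neighbour); intensity transforms touch the image
#' only.
#' \describe{
#'   \item{`mri_flip`}{deterministic left-right flip of the first axis
#'     (an involution: applying it twice restores the pair).}
#'   \item{`ct_full`}{random translation and isotropic scaling about the
#'     grid centre plus additive Gaussian noise and Gaussian blurring; with
#'     all magnitudes zero it is the identity.}
#' }
#'
#' @param vol a [volume()].
#' @param labels a [label_map()] sharing the geometry of `vol`.
#' @param scheme `"mri_flip"` or `"ct_full"`.
#' @param seed optional integer seed for the random draws of `ct_full`.
#' @param translate_max maximum |translation| per axis, voxels.
#' @param scale_range maximum relative deviation of the scale factor.
#' @param noise_sigma additive Gaussian noise s.d.
#' @param blur_sigma_max maximum Gaussian blur s.d. (voxels, in-plane).
#' @return `list(volume =, labels =)`.
#' @export
augment <- function(vol, labels, scheme = c("mri_flip", "ct_full"), seed = NULL,
                    translate_max = 2, scale_range = 0.1,
                    noise_sigma = 0.01, blur_sigma_max = 0.5) {
  scheme <- match.arg(scheme)
  stopifnot(is_volume(vol), is_labelmap(labels))
  stopifnot_same_geometry(vol, labels, "`vol` and `labels`")
  if (scheme == "mri_flip") {
    d <- dim(vol$data)
    v <- vol$data[d[1]:1, , , drop = FALSE]
    l <- labels$data[d[1]:1, , , drop = FALSE]
    return(list(volume = volume(v, vol$spacing, vol$origin),
                labels = label_map(l, labels$spacing, labels$origin, labels$n_classes)))
  }
  if (!is.null(seed)) set.seed(seed)
  d <- dim(vol$data)
  tr <- if (translate_max > 0) runif(3, -translate_max, translate_max) else c(0, 0, 0)
  sc <- if (scale_range > 0) runif(1, 1 - scale_range, 1 + scale_range) else 1
  v <- vol$data
  l <- labels$data
  if (any(tr != 0) || sc != 1) {
    ctr <- (d - 1) / 2
    scale <- rep(1 / sc, 3)
    offset <- ctr - ctr / sc - tr
    v <- array(cpp_affine_sample3d(as.numeric(v), d, d, scale, offset,
                                   mode = 0L, border = 0L, fill = 0), d)
    l <- array(as.integer(cpp_affine_sample3d(as.numeric(l), d, d, scale, offset,
                                              mode = 1L, border = 0L, fill = 0)), d)
  }
  if (blur_sigma_max > 0) {
    s <- runif(1, 0, blur_sigma_max)
    if (s > 1e-3) {
      v <- array(cpp_gaussian_blur3d(as.numeric(v), d, c(s, s, s * vol$spacing[1] / vol$spacing[3])), d)
    }
  }
  if (noise_sigma > 0) v <- v + array(rnorm(length(v), 0, noise_sigma), d)
  list(volume = volume(v, vol$spacing, vol$origin),
       labels = label_map(l, labels$spacing, labels$origin, labels$n_classes))
}
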