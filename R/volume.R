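#' 3D image volume with physical voxel geometry
#'
#' The basic image carrier: a 3D numeric array on a regular grid with a
#' physical voxel spacing and origin in millimetres.  Axis order is
#' (W, H, D) with the third axis the (thick) slice axis; voxel indices are
#' 0-based in all geometric computations and voxel centres sit at
#' `origin + index * spacing`.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, position of voxel (0,0,0) in mm.
#'
#' @return An object of class `segda_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
#' @examples
#' v <- volume(array(rnorm(4 * 4 * 2), c(4, 4, 2)), spacing = c(1, 1, 3))
#' dim(v)
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.", class = "segda_usage_error")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive finite numbers (mm).",
          class = "segda_usage_error")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort("`origin` must be three finite numbers (mm).",
          class = "segda_usage_error")
  }
  if (any(!is.finite(data))) {
    abort("volume data must be finite.", class = "segda_usage_error")
  }
  structure(
    list(data = array(as.numeric(data), dim(data)),
         spacing = spacing, origin = origin),
    class = "segda_volume"
  )
}

#' Multi-class label map
#'
#' Integer per-voxel class assignments over `n_classes` classes
#' (0 = background), sharing the geometry conventions of [volume()].  The
#' sentinel [UNLABELED] (-1) marks voxels carrying no label, as produced
#' for pseudo-labels whose prediction failed the post-processing threshold
#' or was removed by connected-component filtering.
#'
#' @param data 3D integer array with values in `{UNLABELED, 0, ..., n_classes-1}`.
#' @param spacing,origin as in [volume()].
#' @param n_classes number of classes including background (default 4).
#'
#' @return An object of class `segda_labelmap`.
#' @export
label_map <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      n_classes = 4L) {
  if (length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.", class = "segda_usage_error")
  }
  vals <- as.integer(data)
  if (anyNA(vals)) abort("label data must not contain NA.", class = "segda_usage_error")
  if (any(vals < UNLABELED | vals >= n_classes)) {
    abort(sprintf("label values must lie in {%d, 0..%d}.", UNLABELED, n_classes - 1L),
          class = "segda_usage_error")
  }
  v <- volume(array(0, dim(data)), spacing, origin)
  structure(
    list(data = array(vals, dim(data)),
         spacing = v$spacing, origin = v$origin,
         n_classes = as.integer(n_classes)),
    class = "segda_labelmap"
  )
}

#' @export
dim.segda_volume <- function(x) dim(x$data)

#' @export
dim.segda_labelmap <- function(x) dim(x$data)

#' @export
print.segda_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<segda_volume> %d x %d x %d voxels, spacing %s mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.segda_labelmap <- function(x, ...) {
  d <- dim(x)
  tab <- table(factor(x$data, levels = c(UNLABELED, 0:(x$n_classes - 1L))))
  cat(sprintf("<segda_labelmap> %d x %d x %d voxels, %d classes, spacing %s mm\n",
              d[1], d[2], d[3], x$n_classes,
              paste(signif(x$spacing, 4), collapse = " x ")))
  cat("  voxels per value:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

is_volume <- function(x) inherits(x, "segda_volume")
is_labelmap <- function(x) inherits(x, "segda_labelmap")

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_geometry <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b)) {
    abort(paste0(what, " must share grid dimensions, spacing and origin."),
          class = "segda_usage_error")
  }
  invisible(TRUE)
}

#' One-hot encoding of a label map
#'
#' Expands integer labels to a `(n_classes x n_voxels)` indicator matrix.
#' [UNLABELED] voxels get an all-zero column, which is exactly the state the
#' label mask of the partial Dice loss detects.
#'
#' @param labels a [label_map()].
#' @return numeric matrix with one row per class, one column per voxel (in
#'   array order, x fastest).
#' @export
one_hot <- function(labels) {
  stopifnot(is_labelmap(labels))
  C <- labels$n_classes
  v <- as.integer(labels$data)
  Y <- matrix(0, nrow = C, ncol = length(v))
  keep <- v >= 0L
  Y[cbind(v[keep] + 1L, which(keep))] <- 1
  Y
}

#' Probability map over classes
#'
#' Per-voxel, per-class probabilities (a softmax output or an ensemble
#' mean), stored as a `(n_classes x n_voxels)` matrix plus grid geometry.
#'
#' @param probs matrix `(n_classes x n_voxels)`, columns summing to 1.
#' @param dim integer length-3 grid dimensions, `prod(dim) == ncol(probs)`.
#' @param spacing,origin as in [volume()].
#' @return An object of class `segda_probmap`.
#' @export
prob_map <- function(probs, dim, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  if (!is.matrix(probs) || prod(dim) != ncol(probs)) {
    abort("`probs` must be a (classes x voxels) matrix matching `dim`.",
          class = "segda_usage_error")
  }
  if (any(probs < -1e-8) || any(probs > 1 + 1e-8)) {
    abort("probabilities must lie in [0, 1].", class = "segda_usage_error")
  }
  structure(
    list(probs = probs, dim = dim,
         spacing = as.numeric(spacing), origin = as.numeric(origin),
         n_classes = nrow(probs)),
    class = "segda_probmap"
  )
}

#' @export
print.segda_probmap <- function(x, ...) {
  cat(sprintf("<segda_probmap> %s voxels, %d classes\n",
              paste(x$dim, collapse = " x "), x$n_classes))
  invisible(x)
}

#' Hard class assignment (argmax) of a probability map
#'
#' @param mu a [prob_map()].
#' @return a [label_map()] with the per-voxel argmax class.
#' @export
argmax_labels <- function(mu) {
  stopifnot(inherits(mu, "segda_probmap"))
  cls <- max.col(t(mu$probs), ties.method = "first") - 1L
  label_map(array(cls, mu$dim), mu$spacing, mu$origin, n_classes = mu$n_classes)
}

#' Per-class binary mask from a label map
#'
#' @param labels a [label_map()].
#' @param class_id integer class (0-based).
#' @return 3D integer 0/1 array.
#' @export
class_mask <- function(labels, class_id) {
  stopifnot(is_labelmap(labels))
  array(as.integer(labels$data == class_id), dim(labels$data))
}
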