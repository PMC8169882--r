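#' Post-processing policy
#'
#' Controls how a probability map becomes a (pseudo-)label map: the
#' probability threshold, which foreground classes are cleaned by
#' largest-connected-component filtering, and which are exempt.  By
#' default the blob-like and axial-tube classes (1, 2) are filtered while
#' the paired-lateral-tube class (3) is exempt — its fragments are not
#' reliably adjacent across thick slices, so component filtering would
#' discard genuine structure.  Background is never filtered.
#'
#' @param threshold probability threshold in (0, 1); the default 0.5
#'   guarantees at most one class can exceed it for softmax output.
#' @param cc_filtered_classes integer classes to component-filter.
#' @param cc_exempt_classes integer classes exempt from filtering (must be
#'   disjoint from `cc_filtered_classes`).
#' @param connectivity 6, 18 or 26 (full 3D) neighbourhood.
#' @return an object of class `segda_postprocess_policy`.
#' @export
postprocess_policy <- function(threshold = 0.5,
                               cc_filtered_classes = c(1L, 2L),
                               cc_exempt_classes = 3L,
                               connectivity = 26L) {
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie in (0, 1).", class = "segda_usage_error")
  }
  if (length(intersect(cc_filtered_classes, cc_exempt_classes))) {
    abort("filtered and exempt class sets must be disjoint.",
          class = "segda_usage_error")
  }
  if (!connectivity %in% c(6L, 18L, 26L)) {
    abort("`connectivity` must be 6, 18 or 26.", class = "segda_usage_error")
  }
  structure(
    list(threshold = threshold,
         cc_filtered_classes = as.integer(cc_filtered_classes),
         cc_exempt_classes = as.integer(cc_exempt_classes),
         connectivity = as.integer(connectivity)),
    class = "segda_postprocess_policy"
  )
}

#' Threshold a probability map into labels with explicit unlabeled voxels
#'
#' A voxel is assigned the argmax class among those whose probability
#' exceeds the threshold; if no class exceeds it, the voxel becomes
#' [UNLABELED].  (With `threshold >= 0.5` at most one class can exceed it,
#' making the binarization unambiguous.)
#'
#' @param mu a [prob_map()].
#' @param threshold scalar in (0, 1).
#' @return a [label_map()] possibly containing [UNLABELED].
#' @export
threshold_labels <- function(mu, threshold = 0.5) {
  stopifnot(inherits(mu, "segda_probmap"))
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie in (0, 1).", class = "segda_usage_error")
  }
  p <- mu$probs
  masked <- p * (p > threshold)
  best <- max.col(t(masked), ties.method = "first")
  any_exceeds <- colSums(p > threshold) > 0
  cls <- ifelse(any_exceeds, best - 1L, UNLABELED)
  label_map(array(as.integer(cls), mu$dim), mu$spacing, mu$origin,
            n_classes = mu$n_classes)
}

#' Keep only the largest connected component of a binary mask
#'
#' Components are found with the given 3D connectivity; size ties are
#' broken deterministically in favour of the component whose first voxel
#' comes earliest in raster-scan order.  An empty mask is returned
#' unchanged.
#'
#' @param mask 3D binary (0/1 integer) array.
#' @param connectivity 6, 18 or 26.
#' @return 3D binary array of the same shape.
#' @export
keep_largest_component <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  if (length(d) != 3L) abort("`mask` must be a 3D array.", class = "segda_usage_error")
  lab <- cpp_label_components(as.integer(mask != 0), d, as.integer(connectivity))
  if (all(lab == 0L)) return(array(0L, d))
  sizes <- tabulate(lab)
  array(as.integer(lab == which.max(sizes)), d)
}

#' Post-process a probability map into a pseudo-label map
#'
#' Thresholds the probabilities (see [threshold_labels()]) and then, for
#' each class in the policy's filtered set, keeps only the largest
#' connected component; voxels whose label is removed by the filtering
#' become [UNLABELED] rather than background, so they are excluded from
#' the partial Dice loss instead of acting as negative evidence.  Exempt
#' classes and background pass through untouched.  Post-processing never
#' adds labeled voxels.
#'
#' @param mu a [prob_map()].
#' @param policy a [postprocess_policy()].
#' @return a [label_map()] possibly containing [UNLABELED].
#' @export
postprocess_prediction <- function(mu, policy = postprocess_policy()) {
  stopifnot(inherits(policy, "segda_postprocess_policy"))
  labels <- threshold_labels(mu, policy$threshold)
  data <- labels$data
  for (cl in policy$cc_filtered_classes) {
    mask <- array(as.integer(data == cl), dim(data))
    if (!any(mask == 1L)) next
    kept <- keep_largest_component(mask, policy$connectivity)
    removed <- mask == 1L & kept == 0L
    data[removed] <- UNLABELED
  }
  label_map(data, labels$spacing, labels$origin, labels$n_classes)
}
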