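#' Dice similarity coefficient of two binary masks
#'
#' `DSC = 2|X ∩ Y| / (|X| + |Y|)`.  Conventions for empty masks: both
#' empty gives 1 (perfect agreement), exactly one empty gives 0.
#'
#' @param X,Y 3D binary arrays of identical dimensions (prediction and
#'   ground truth).
#' @return scalar in `[0, 1]`.
#' @export
dsc <- function(X, Y) {
  if (!identical(dim(X), dim(Y))) {
    abort("`X` and `Y` must share dimensions.", class = "segda_usage_error")
  }
  x <- X != 0
  y <- Y != 0
  nx <- sum(x)
  ny <- sum(y)
  if (nx + ny == 0) return(1)
  2 * sum(x & y) / (nx + ny)
}

#' Average boundary distance between two binary masks, in mm
#'
#' Surface voxels are foreground voxels with at least one face-adjacent
#' background neighbour (the grid boundary counts as background).  The ABD
#' is the symmetric sum of directed minimum Euclidean distances between
#' the two surface point sets, divided by the total number of surface
#' points:
#' `ABD = (sum_x min_y d(x,y) + sum_y min_x d(y,x)) / (|X_S| + |Y_S|)`,
#' with distances measured between voxel centres in physical mm.
#'
#' @param X,Y 3D binary arrays of identical dimensions.
#' @param spacing voxel spacing in mm.
#' @return scalar mm, or `NA` when either mask is empty (undefined).
#' @export
abd <- function(X, Y, spacing = c(1, 1, 1)) {
  if (!identical(dim(X), dim(Y))) {
    abort("`X` and `Y` must share dimensions.", class = "segda_usage_error")
  }
  d <- dim(X)
  sx <- cpp_surface_voxels(as.integer(X != 0), d)
  sy <- cpp_surface_voxels(as.integer(Y != 0), d)
  if (nrow(sx) == 0 || nrow(sy) == 0) return(NA_real_)
  (cpp_sum_min_dists(sx, sy, as.numeric(spacing)) +
     cpp_sum_min_dists(sy, sx, as.numeric(spacing))) /
    (nrow(sx) + nrow(sy))
}

#' Per-class evaluation of a predicted label map against ground truth
#'
#' Computes DSC and ABD for every foreground class.  [UNLABELED] voxels in
#' the prediction count as background.  A class absent from the ground
#' truth is flagged (`gt_present = FALSE`) so it can be excluded from
#' aggregates; a structure missed entirely by the prediction has DSC 0 and
#' an undefined (NA) ABD.
#'
#' @param pred a [label_map()] (may contain [UNLABELED]).
#' @param gt a fully labeled [label_map()] with the same geometry.
#' @param classes integer foreground classes to evaluate (default: all
#'   non-background classes of `gt`).
#' @param case_id optional case identifier recorded in the output.
#' @return tibble with columns `case_id`, `class`, `dsc`, `abd_mm`,
#'   `gt_present`.
#' @export
evaluate_case <- function(pred, gt, classes = NULL, case_id = NA_character_) {
  stopifnot(is_labelmap(pred), is_labelmap(gt))
  stopifnot_same_geometry(pred, gt, "`pred` and `gt`")
  if (any(gt$data == UNLABELED)) {
    abort("`gt` must be fully labeled.", class = "segda_usage_error")
  }
  classes <- classes %||% seq_len(gt$n_classes - 1L)
  rows <- lapply(classes, function(cl) {
    pm <- pred$data == cl          # UNLABELED (-1) never equals a class id
    gm <- gt$data == cl
    present <- any(gm)
    tibble(case_id = case_id, class = as.integer(cl),
           dsc = if (present || any(pm)) dsc(pm, gm) else 1,
           abd_mm = abd(pm, gm, gt$spacing),
           gt_present = present)
  })
  dplyr::bind_rows(rows)
}

#' Evaluate predictions over a set of cases
#'
#' @param preds named list of predicted [label_map()]s.
#' @param gts named list of ground-truth [label_map()]s (same names).
#' @param classes foreground classes to evaluate.
#' @return an object of class `segda_metrics`: a tibble of per-case rows
#'   (see [evaluate_case()]).
#' @export
evaluate_cases <- function(preds, gts, classes = NULL) {
  ids <- names(preds) %||% as.character(seq_along(preds))
  rows <- purrr::pmap(list(preds, gts, ids), function(p, g, id) {
    evaluate_case(p, g, classes = classes, case_id = id)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("segda_metrics", class(out))
  out
}

#' Aggregate a metrics table per class
#'
#' Mean and median DSC/ABD per class over cases, excluding rows whose
#' class is absent from the ground truth; undefined ABDs are dropped from
#' the ABD aggregates (their count is reported).
#'
#' @param metrics a tibble from [evaluate_cases()] / [evaluate_case()].
#' @return tibble with one row per class.
#' @export
aggregate_metrics <- function(metrics) {
  metrics |>
    dplyr::filter(.data$gt_present) |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(
      n_cases = dplyr::n(),
      mean_dsc = mean(.data$dsc),
      median_dsc = stats::median(.data$dsc),
      mean_abd_mm = mean(.data$abd_mm, na.rm = TRUE),
      median_abd_mm = stats::median(.data$abd_mm, na.rm = TRUE),
      n_abd_undefined = sum(is.na(.data$abd_mm)),
      .groups = "drop"
    )
}

#' Write a metrics report to CSV plus a JSON aggregate block
#'
#' @param metrics a tibble from [evaluate_cases()].
#' @param csv_path per-case CSV destination.
#' @param json_path aggregate JSON destination (optional).
#' @return the aggregate tibble, invisibly.
#' @export
write_metrics_report <- function(metrics, csv_path, json_path = NULL) {
  readr::write_csv(metrics, csv_path)
  agg <- aggregate_metrics(metrics)
  if (!is.null(json_path)) {
    jsonlite::write_json(agg, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(agg)
}
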