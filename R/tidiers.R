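#' Tidy a segmentation model into a per-tensor summary
#'
#' @param x a `segda_model`.
#' @param ... unused.
#' @return tibble with one row per parameter tensor: `tensor`, `group`,
#'   `n_params`.
#' @export
tidy.segda_model <- function(x, ...) {
  groups <- parameter_groups(x)
  lookup <- unlist(lapply(names(groups), function(g) {
    setNames(rep(g, length(groups[[g]])), groups[[g]])
  }))
  tibble(
    tensor = names(x$params),
    group = unname(lookup[names(x$params)]),
    n_params = vapply(x$params, length, 0L)
  )
}

#' One-row summary of a segmentation model
#'
#' @param x a `segda_model`.
#' @param ... unused.
#' @return tibble with the architecture fingerprint (total and per-group
#'   parameter counts) and, when the model was trained, its best epoch and
#'   validation metrics.
#' @export
glance.segda_model <- function(x, ...) {
  gc <- group_parameter_counts(x)
  out <- tibble(
    levels = x$spec$levels,
    base_filters = x$spec$base_filters,
    bottom_filters = x$spec$bottom_filters,
    n_classes = x$spec$n_classes,
    n_params = count_parameters(x),
    n_params_encoder = gc[["encoder"]],
    n_params_bottleneck = gc[["bottleneck"]],
    n_params_decoder = gc[["decoder"]]
  )
  if (!is.null(x$history) && nrow(x$history)) {
    best <- x$history[x$best_epoch, ]
    out$epochs_trained <- nrow(x$history)
    out$best_epoch <- x$best_epoch
    out$val_loss <- best$val_loss
    out$val_dsc <- best$val_dsc
  }
  out
}

#' Tidy an ensemble into a per-member summary
#'
#' @param x a `segda_ensemble`.
#' @param ... unused.
#' @return tibble with one row per member.
#' @export
tidy.segda_ensemble <- function(x, ...) {
  rows <- purrr::imap(x$members, function(m, i) {
    g <- glance(m)
    dplyr::bind_cols(tibble(member = as.integer(i), seed = x$seeds[i]), g)
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of an ensemble
#'
#' @param x a `segda_ensemble`.
#' @param ... unused.
#' @return tibble with the ensemble size and parameter count per member.
#' @export
glance.segda_ensemble <- function(x, ...) {
  tibble(k = length(x$members),
         n_params_per_member = count_parameters(x$members[[1]]),
         seeds = paste(x$seeds, collapse = ","))
}

#' One-row summary of a metrics table
#'
#' @param x a `segda_metrics` tibble.
#' @param ... unused.
#' @return tibble with overall mean DSC/ABD over evaluable rows.
#' @export
glance.segda_metrics <- function(x, ...) {
  ok <- x[x$gt_present, ]
  tibble(n_cases = length(unique(ok$case_id)),
         n_rows = nrow(ok),
         mean_dsc = mean(ok$dsc),
         mean_abd_mm = mean(ok$abd_mm, na.rm = TRUE))
}
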