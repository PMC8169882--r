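#' Plot an axial slice of a volume with optional label overlay
#'
#' @param vol a [volume()].
#' @param labels optional [label_map()] overlaid with per-class colours
#'   (background transparent).
#' @param z 1-based slice index (default: middle slice).
#' @return a ggplot object.
#' @export
plot_slice <- function(vol, labels = NULL, z = NULL) {
  stopifnot(is_volume(vol))
  d <- dim(vol$data)
  z <- z %||% ceiling(d[3] / 2)
  df <- tidyr::expand_grid(y = seq_len(d[2]), x = seq_len(d[1]))
  df$intensity <- as.vector(vol$data[, , z])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed(ratio = vol$spacing[2] / vol$spacing[1]) +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(labels)) {
    lf <- df
    lf$class <- as.vector(labels$data[, , z])
    lf <- lf[lf$class > 0, , drop = FALSE]
    if (nrow(lf)) {
      p <- p + ggplot2::geom_tile(
        data = lf,
        ggplot2::aes(.data$x, .data$y, colour = factor(.data$class)),
        fill = NA, linewidth = 0.2, inherit.aes = FALSE) +
        ggplot2::labs(colour = "class")
    }
  }
  p
}

#' Plot per-class segmentation quality
#'
#' Boxplots of the per-case DSC for each evaluated class.
#'
#' @param object a `segda_metrics` tibble from [evaluate_cases()].
#' @param metric `"dsc"` or `"abd_mm"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.segda_metrics <- function(object, metric = c("dsc", "abd_mm"), ...) {
  metric <- match.arg(metric)
  df <- object[object$gt_present, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$class), .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "class", y = metric) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Training and validation loss (and validation DSC) per epoch for a
#' trained model.
#'
#' @param model a `segda_model` returned by [train_model()].
#' @return a ggplot object.
#' @export
plot_training_history <- function(model) {
  if (is.null(model$history) || !nrow(model$history)) {
    abort("the model has no training history.", class = "segda_usage_error")
  }
  df <- model$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss", "val_dsc"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal() +
    ggplot2::labs(y = NULL)
}
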