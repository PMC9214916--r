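#' Plot a feature dictionary
#'
#' One panel per internal-coordinate family: each bin's maximum is drawn
#' as a point at its location, with a horizontal segment spanning its
#' finite assignment interval. A quick way to see how many peaks each
#' class contributed.
#'
#' @param object A `feature_dictionary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_dictionary <- function(object, ...) {
  bins <- object$bins
  if (!nrow(bins)) stop("dictionary has no KDE bins to plot", call. = FALSE)
  rng <- bins |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(
      lo = ifelse(is.finite(.data$lower), .data$lower,
                  min(.data$maximum) - 0.05 * diff(range(.data$maximum, 1))),
      hi = ifelse(is.finite(.data$upper), .data$upper,
                  max(.data$maximum) + 0.05 * diff(range(.data$maximum, 1)))
    ) |>
    dplyr::ungroup()
  ggplot2::ggplot(rng, ggplot2::aes(y = .data$class_label)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       yend = .data$class_label),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$maximum), size = 1.6) +
    ggplot2::facet_wrap(~family, scales = "free") +
    ggplot2::labs(x = "bin maximum and assignment interval",
                  y = NULL,
                  title = "KDE feature bins by class") +
    ggplot2::theme_minimal()
}

#' Plot a learning curve
#'
#' @param curve Tibble from [learning_curve()] (`size`, `mae`), optionally
#'   with extra grouping columns (e.g. `family`).
#' @return A ggplot object (log-log axes, the conventional scale for
#'   learning curves).
#' @export
plot_learning_curve <- function(curve) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$size, y = .data$mae))
  if ("family" %in% names(curve)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$family)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$family))
  } else {
    p <- p + ggplot2::geom_line() + ggplot2::geom_point()
  }
  p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "training molecules", y = "test MAE (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Plot predicted vs. true energies of a pipeline result
#'
#' @param object A `pipeline_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pipeline_result <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$truth, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "reference energy (kcal/mol)",
                  y = "predicted energy (kcal/mol)",
                  subtitle = sprintf("test MAE %.3f kcal/mol", object$test_mae)) +
    ggplot2::theme_minimal()
}
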