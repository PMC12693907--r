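# broom-style accessors and plotting for fitted models and simulator output.

#' Tidy a fitted model's training history
#'
#' @param x A `ripecast_model`.
#' @param ... Unused.
#' @return Tibble with `epoch` and `loss`.
#' @export
tidy.ripecast_model <- function(x, ...) {
  x$history
}

#' One-row model summary
#'
#' @param x A `ripecast_model`.
#' @param ... Unused.
#' @return Tibble with model class, parameter count, epochs trained, and
#'   final training loss.
#' @export
glance.ripecast_model <- function(x, ...) {
  tibble::tibble(
    model = class(x)[1],
    n_parameters = sum(vapply(x$params, length, integer(1))),
    epochs_trained = nrow(x$history),
    final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)] else NA_real_)
}

#' Training loss curve
#'
#' @param object A trained `ripecast_model`.
#' @param ... Unused.
#' @return A ggplot of loss against epoch (log scale).
#' @export
autoplot.ripecast_model <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "training loss (MSE)",
                  title = sprintf("%s training history", class(object)[1])) +
    ggplot2::theme_minimal()
}

#' Plot a simulated or predicted color trajectory
#'
#' @param colors Tibble with `timestamp`, `red`, `yellow`, `green` (and
#'   optionally `plant_id` for faceting).
#' @return A ggplot of the three surface fractions over time.
#' @export
plot_color_trajectory <- function(colors) {
  long <- tidyr::pivot_longer(colors, dplyr::all_of(c("red", "yellow", "green")),
                              names_to = "class", values_to = "fraction")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$timestamp,
                                          y = .data$fraction,
                                          color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(red = "#b2182b", yellow = "#e6b800",
                                           green = "#1b7837")) +
    ggplot2::labs(y = "surface fraction") +
    ggplot2::theme_minimal()
  if ("plant_id" %in% names(colors)) {
    p <- p + ggplot2::facet_wrap(~plant_id)
  }
  p
}

#' Plot observed against predicted values
#'
#' @param truth,estimate Numeric vectors.
#' @param label Axis label (target name and units).
#' @return A ggplot scatter with the identity line.
#' @export
plot_pred_obs <- function(truth, estimate, label = "value") {
  df <- tibble::tibble(truth = truth, estimate = estimate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.6, color = "#2166ac") +
    ggplot2::labs(x = sprintf("observed %s", label),
                  y = sprintf("predicted %s", label)) +
    ggplot2::theme_minimal()
}
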