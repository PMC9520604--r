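#' @exportS3Method ggplot2::autoplot
autoplot.walk_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time step", y = "position") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.spike_raster <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$neuron)) +
    ggplot2::geom_point(shape = ".", colour = "blue") +
    ggplot2::coord_cartesian(xlim = c(1, attr(object, "n_bins")),
                             ylim = c(1, attr(object, "n_neurons"))) +
    ggplot2::labs(x = "time bin", y = "neuron") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.avalanche_set <- function(object,
                                   which = c("size", "duration"), ...) {
  which <- match.arg(which)
  x <- object[[which]]
  tab <- table(x)
  df <- tibble(value = as.numeric(names(tab)),
               prob = as.numeric(tab) / length(x))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$prob)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste("avalanche", which), y = "probability") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.collapse_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$u, y = .data$height,
                               colour = factor(.data$duration))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t / T", y = expression(h / T^{gamma - 1}),
                  colour = "T",
                  subtitle = sprintf("gamma = %.2f, collapse error = %.3g",
                                     object$gamma_used,
                                     object$collapse_error)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.hurst_estimate <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$window_length, y = .data$mean_std)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "window length L", y = "mean within-window STD",
                  subtitle = sprintf("H = %.3f", object$H)) +
    ggplot2::theme_minimal()
}

#' Plot a control-parameter sweep
#'
#' Convenience line plot of any per-`g` quantity from the sweep tibbles
#' (e.g. `firing_rate` or `tau_decay` from [sweep_decay()], `mi_mean` from
#' [sweep_mi()]).
#'
#' @param data A sweep tibble with a `g` column.
#' @param y Column to plot (character).
#' @param colour Optional grouping column (character), e.g. `"size"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(data, y, colour = NULL) {
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$g, y = .data[[y]]))
  if (!is.null(colour))
    p <- p + ggplot2::aes(colour = factor(.data[[colour]]))
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = 3, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "relative inhibition g", colour = colour) +
    ggplot2::theme_minimal()
}
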