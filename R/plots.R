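#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a passage curve
#'
#' Cumulative passage fraction against normalised time (`t / t_end`).
#'
#' @param object A `passage_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.passage_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_norm, y = .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = expression(t / t[c]), y = expression(N[pt] / N[p0])) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a Hill fit over its data
#'
#' The fitted Hill curve drawn through the passage data it was fitted to,
#' on a logarithmic time axis.
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hill_fit <- function(object, ...) {
  df <- object$data
  tgrid <- exp(seq(log(min(df$t)), log(max(df$t)), length.out = 200))
  fitdf <- data.frame(t = tgrid,
                      f = hill_fraction(tgrid, object$D_eff, object$n, object$h))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$f)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = fitdf, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (s)", y = expression(N[pt] / N[p0]),
                  subtitle = sprintf("D_eff = %.3g m²/s, n = %.3g, R² = %.4f",
                                     object$D_eff, object$n, object$r_squared)) +
    ggplot2::theme_minimal()
}
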