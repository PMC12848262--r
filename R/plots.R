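#' Plot an excretion curve
#'
#' @param object An `excretion_curve`.
#' @param t_max Right edge of the time axis, days (default 1.5).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.excretion_curve <- function(object, t_max = 1.5, ...) {
  grid <- tibble::tibble(time_h = seq(0, t_max * 24, length.out = 400))
  grid$ratio <- curve_value(object, grid$time_h / 24)
  ggplot2::ggplot(grid, ggplot2::aes(.data$time_h, .data$ratio)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Time post-dose (h)",
                  y = "Co:creatinine ratio (mg/mg)") +
    ggplot2::theme_minimal()
}

#' Observed versus fitted ratios for a population fit
#'
#' Scatter of observed Co:creatinine ratios against each animal's
#' empirical-Bayes fitted values, with the x = y line — the standard
#' graphical adequacy check.
#'
#' @param object An `saem_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saem_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(.data$.fitted, .data$ratio)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Fitted Co:creatinine ratio (mg/mg)",
                  y = "Observed Co:creatinine ratio (mg/mg)") +
    ggplot2::theme_minimal()
}

#' Normal QQ plot of npde
#'
#' @param object An `npde_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.npde_report <- function(object, ...) {
  ggplot2::ggplot(object$npde, ggplot2::aes(sample = .data$npde)) +
    ggplot2::geom_qq_line(linetype = 2, colour = "grey50") +
    ggplot2::geom_qq(alpha = 0.7) +
    ggplot2::labs(x = "Standard normal quantiles", y = "npde") +
    ggplot2::theme_minimal()
}
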