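#' Plot a predicted risk curve
#'
#' @param object An `ova_risk_curve` from [future_risk()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ova_risk_curve <- function(object, ...) {
  cond <- attr(object, "conditioning")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$risk)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.1f%%", 100 * x)) +
    ggplot2::labs(
      x = "Age (years)", y = "Cumulative ovarian-cancer risk",
      title = sprintf("Predicted risk from age %d", cond$from_age),
      subtitle = if (!is.null(cond$prs)) sprintf("PRS = %.3f", cond$prs) else NULL
    ) +
    ggplot2::theme_minimal()
}

#' Compare risk curves across scenarios
#'
#' @param curves Named list of `ova_risk_curve` objects.
#' @return A ggplot with one line per scenario.
#' @export
plot_risk_comparison <- function(curves) {
  df <- dplyr::bind_rows(lapply(curves, tibble::as_tibble), .id = "scenario")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$risk,
                                   colour = .data$scenario)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.1f%%", 100 * x)) +
    ggplot2::labs(x = "Age (years)", y = "Cumulative ovarian-cancer risk",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a risk concentration curve
#'
#' Fraction of cases accounted for by the fraction of the population above
#' each risk threshold; the diagonal is the no-discrimination reference.
#'
#' @param object An `ova_concentration` from [concentration_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ova_concentration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pop_fraction,
                                       y = .data$case_fraction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "Proportion of population at highest risk",
      y = "Proportion of cases accounted for",
      title = sprintf("Risk concentration (sigma = %.3f)", object$sigma[1])
    ) +
    ggplot2::theme_minimal()
}
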