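#' Dose-response plot of cell means from an ANOVA fit
#'
#' @param object An `rm_anova` fit.
#' @param ... Unused.
#' @return A ggplot: dose on x, cell mean on y, one line per diet.
#' @export
autoplot.rm_anova <- function(object, ...) {
  ggplot2::ggplot(object$means,
                  ggplot2::aes(x = .data$dose, y = .data$mean,
                               colour = .data$diet, group = .data$diet)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "dose period", y = "mean response", colour = "diet") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot daily gas emissions by period and diet
#'
#' @param emissions Output of [daily_emission()] (with a `diet` column for
#'   facetting, if available).
#' @param yield Plot g/kg DMI (`TRUE`, default) or g/day.
#' @return A ggplot of per-animal points with group-mean lines, one facet
#'   per gas.
#' @export
plot_emissions <- function(emissions, yield = TRUE) {
  ycol <- if (yield) "g_per_kg_dmi" else "g_day"
  p <- ggplot2::ggplot(emissions,
                       ggplot2::aes(x = .data$period, y = .data[[ycol]])) +
    ggplot2::geom_point(alpha = 0.6, position = ggplot2::position_jitter(
      width = 0.08, height = 0)) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", colour = "steelblue") +
    ggplot2::labs(x = "period",
                  y = if (yield) "yield (g/kg DMI)" else "production (g/day)") +
    ggplot2::theme_minimal()
  if ("diet" %in% names(emissions)) {
    p + ggplot2::facet_grid(ggplot2::vars(.data$gas),
                            ggplot2::vars(.data$diet), scales = "free_y")
  } else {
    p + ggplot2::facet_wrap(ggplot2::vars(.data$gas), scales = "free_y")
  }
}

#' Plot hydrogen-redirection summaries
#'
#' @param balance Output of [hydrogen_balance()] (ideally after
#'   [husr_change_vs_control()]) with `period` and `diet` columns.
#' @param what One of `"husr_change"`, `"formate_to_scfa_h"`,
#'   `"non_carboxyl_carbon"`.
#' @return A ggplot of per-period group means with points.
#' @export
plot_hydrogen_balance <- function(balance,
                                  what = c("husr_change", "formate_to_scfa_h",
                                           "non_carboxyl_carbon")) {
  what <- match.arg(what)
  col <- switch(what, husr_change = "husr_change_pct", what)
  lab <- switch(what,
                husr_change = "[H] into SCFA, % change vs control",
                formate_to_scfa_h = "HUFr / HUSr",
                non_carboxyl_carbon = "non-carboxyl SCFA carbon (mM)")
  df <- filter(balance, !is.na(.data[[col]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data[[col]],
                                   fill = .data$diet)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          position = ggplot2::position_dodge(0.8),
                          width = 0.7) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.8),
                        alpha = 0.5, show.legend = FALSE) +
    ggplot2::labs(x = "period", y = lab, fill = "diet") +
    ggplot2::theme_minimal()
}

#' Plot community ratio trajectories over periods
#'
#' @param ratios Output of [taxon_ratios()].
#' @return A ggplot of per-period mean ratios, one facet per preset index.
#' @export
plot_community_ratios <- function(ratios) {
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$period, y = .data$ratio)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean, geom = "line",
                          colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$preset), scales = "free_y") +
    ggplot2::labs(x = "period", y = "ratio") +
    ggplot2::theme_minimal()
}
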