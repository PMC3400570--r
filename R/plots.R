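#' Plot a cost-effectiveness acceptability curve
#'
#' Probability the intervention is cost-effective against the ceiling
#' ratio, one line per `label`, with the 0.5 reference line where the curve
#' crosses the ICER.
#'
#' @param object A `ceac_curve` tibble (possibly multi-label).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ceac_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ro, y = .data$prob_ce,
                                       colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Ceiling ratio Ro (CFA per facility delivery)",
                  y = "P(intervention cost-effective)",
                  colour = NULL,
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Plot a net-benefit regression grid
#'
#' Incremental net benefit (the treatment coefficient) against the ceiling
#' ratio with a pointwise 95% band.
#'
#' @param object An `nb_grid` from [nb_regression_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.nb_grid <- function(object, ...) {
  sci <- as_tibble(object)[object$term == "sci", ]
  ggplot2::ggplot(sci, ggplot2::aes(x = .data$ro, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$estimate - 1.96 * .data$std.error,
      ymax = .data$estimate + 1.96 * .data$std.error), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Ceiling ratio Ro (CFA per facility delivery)",
                  y = "Incremental net benefit (CFA)",
                  title = "Net-benefit regression across ceiling ratios") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane
#'
#' Plots incremental effect against incremental cost with the four
#' quadrants annotated; accepts one or more `icer_result` rows (e.g. the
#' overall ICER plus the strata).
#'
#' @param icer_result An `icer_result` tibble from [icer()] or
#'   [stratified_icer()].
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(icer_result) {
  df <- as_tibble(icer_result)
  df <- df[!is.na(df$delta_e), ]
  df$stratum <- ifelse(is.na(df$stratum), "overall", df$stratum)
  lim_e <- max(abs(df$delta_e)) * 1.3
  lim_c <- max(abs(df$delta_c)) * 1.3
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_e, y = .data$delta_c,
                                   colour = .data$stratum)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::annotate("text", x = lim_e, y = lim_c, hjust = 1, vjust = 1,
                      label = "NE: trade-off", colour = "grey30", size = 3) +
    ggplot2::annotate("text", x = lim_e, y = -lim_c, hjust = 1, vjust = 0,
                      label = "SE: dominant", colour = "grey30", size = 3) +
    ggplot2::annotate("text", x = -lim_e, y = lim_c, hjust = 0, vjust = 1,
                      label = "NW: dominated", colour = "grey30", size = 3) +
    ggplot2::annotate("text", x = -lim_e, y = -lim_c, hjust = 0, vjust = 0,
                      label = "SW: trade-off", colour = "grey30", size = 3) +
    ggplot2::expand_limits(x = c(-lim_e, lim_e), y = c(-lim_c, lim_c)) +
    ggplot2::labs(x = "Incremental effect (facility-delivery proportion)",
                  y = "Incremental cost (CFA)", colour = NULL,
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}
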