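# ggplot2 graphics for the main result types

#' @exportS3Method ggplot2::autoplot
autoplot.effect_curve <- function(object, ...) {
  pts <- tibble(dose = object$dose, mean_effect = object$mean_effect,
                se = object$se)
  d0 <- c(0, object$dose)
  m0 <- c(0, object$mean_effect)
  sf <- splinefun(d0, m0, method = "monoH.FC")
  line <- tibble(dose = seq(0, max(d0), length.out = 200))
  line$effect <- sf(line$dose)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$dose)) +
    ggplot2::geom_line(data = line, ggplot2::aes(y = .data$effect),
                       color = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_effect - .data$se,
                                        ymax = .data$mean_effect + .data$se),
                           width = 0, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_effect)) +
    ggplot2::labs(x = "dose (µM)", y = "effect (%)",
                  title = sprintf("Dose-effect curve: %s", attr(object, "agent")),
                  subtitle = "points: per-dose means ± SE; line: monotone piecewise-cubic interpolant")
}

#' @exportS3Method ggplot2::autoplot
autoplot.isobole_envelope <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$dose_a)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$line)) +
    ggplot2::labs(x = sprintf("%s dose (µM)", object$agent_a),
                  y = sprintf("%s dose (µM)", object$agent_b),
                  title = sprintf("Additivity isobole at E = %g%%", object$effect),
                  subtitle = sprintf("%g%% pointwise bootstrap envelope",
                                     100 * object$conf_level))
}

#' Isobologram of a synergy assessment
#'
#' One panel per analysis effect level: the additivity line between the two
#' ED intercepts, its pointwise bootstrap confidence envelope, and the
#' combination dose point.
#'
#' @param object A [assess_synergy()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.synergy_assessment <- function(object, ...) {
  grids <- purrr::map_dfr(object$envelopes, function(e) {
    dplyr::mutate(e$grid, effect = e$effect)
  })
  grids$panel <- sprintf("E = %g%%", grids$effect)
  pt <- tibble(dose_a = object$combo_dose[["a"]],
               dose_b = object$combo_dose[["b"]],
               panel = sprintf("E = %g%%", object$levels$effect),
               verdict = object$levels$verdict)
  ggplot2::ggplot(grids, ggplot2::aes(x = .data$dose_a)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$line)) +
    ggplot2::geom_point(data = pt,
                        ggplot2::aes(y = .data$dose_b, color = .data$verdict),
                        size = 3) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = sprintf("%s dose (µM)", object$agents[["a"]]),
                  y = sprintf("%s dose (µM)", object$agents[["b"]]),
                  title = sprintf("Isobolographic analysis: %s + %s",
                                  object$agents[["a"]], object$agents[["b"]]))
}

#' Group tumor-growth curves
#'
#' Mean tumor volume per group over time with standard-error bars.
#'
#' @param series A [tumor_series()] tibble.
#' @return A ggplot object.
#' @export
plot_tumor_growth <- function(series) {
  summ <- dplyr::summarise(dplyr::group_by(series, .data$group, .data$day),
                           mean_volume = mean(.data$volume),
                           se = sd(.data$volume) / sqrt(dplyr::n()),
                           .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$day, y = .data$mean_volume,
                                     color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_volume - .data$se,
                                          ymax = .data$mean_volume + .data$se),
                             size = 0.3) +
    ggplot2::labs(x = "day", y = expression("tumor volume (mm"^3 * ")"),
                  color = "group", title = "Xenograft tumor growth")
}
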