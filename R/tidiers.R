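# broom-style tidiers

#' @exportS3Method generics::tidy
tidy.dose_linfit <- function(x, ...) {
  tibble(term = c("(Intercept)", "dose"),
         estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.dose_linfit <- function(x, ...) {
  tibble(agent = x$agent, r_squared = x$r_squared, statistic = x$statistic,
         p_value = x$p_value, n = x$n)
}

#' @exportS3Method generics::tidy
tidy.ed_estimate <- function(x, ...) {
  tibble(agent = x$agent, effect = x$effect, estimate = x$estimate,
         conf_low = x$conf_low, conf_high = x$conf_high,
         conf_level = x$conf_level, B = x$B, n_unreachable = x$n_unreachable)
}

#' @exportS3Method generics::tidy
tidy.potency_ratio <- function(x, ...) {
  tibble(agent_a = x$agent_a, agent_b = x$agent_b, effect = x$effect,
         estimate = x$ratio, conf_low = x$conf_low, conf_high = x$conf_high)
}

#' @exportS3Method generics::tidy
tidy.synergy_assessment <- function(x, ...) {
  dplyr::mutate(x$levels,
                agent_a = x$agents[["a"]], agent_b = x$agents[["b"]],
                dose_a = x$combo_dose[["a"]], dose_b = x$combo_dose[["b"]],
                .before = 1)
}

#' @exportS3Method generics::glance
glance.synergy_assessment <- function(x, ...) {
  final <- x$levels[x$levels$effect == x$analysis_level, ]
  tibble(combo_effect = x$combo$mean, combo_se = x$combo$se, combo_n = x$combo$n,
         escalation_p = x$escalation$p_value, analysis_level = x$analysis_level,
         r50 = x$r50$ratio, r_max = x$r_max$ratio, max_common_effect = x$r_max$effect,
         g_statistic = x$constancy$statistic, g_p_value = x$constancy$p_value,
         linear_isobole = x$constancy$linear_isobole,
         gamma = final$gamma, verdict = x$verdict)
}

#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) {
  if (is.null(x$anova)) {
    tibble(day = x$day, n_groups = length(x$groups),
           statistic = x$pairwise$statistic[1], df1 = NA_real_,
           df2 = x$pairwise$df[1], p_value = x$pairwise$p_value[1],
           method = "pooled t-test")
  } else {
    tibble(day = x$day, n_groups = length(x$groups),
           statistic = x$anova$statistic, df1 = x$anova$df1,
           df2 = x$anova$df2, p_value = x$anova$p_value,
           method = "one-way ANOVA")
  }
}
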