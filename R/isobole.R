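# Loewe-additivity synergy engine: potency ratios and their constancy,
# additivity isoboles with bootstrap confidence envelopes, interaction index,
# effect-level escalation, and combination classification.

#' Potency ratio of two agents at a common effect level
#'
#' `R_E = ED_E(A) / ED_E(B)`, the relative potency of the two agents at
#' effect level E. Constancy of `R_E` across effect levels is what justifies
#' a linear additivity isobole. When both estimates carry paired bootstrap
#' draws (from [bootstrap_ed()] or [assess_synergy()]), a percentile CI of
#' the ratio is attached by pairing resamples.
#'
#' @param ed_a,ed_b `ed_estimate` objects at the same effect level.
#' @param conf_level Confidence level for the ratio CI.
#' @return A `potency_ratio` object.
#' @examples
#' ed_nx <- interpolate_ed(effect_curve(data.frame(dose = c(20, 51, 80),
#'                                                 effect = c(19.6, 50, 78.4)), "naloxone"), 50)
#' ed_cis <- interpolate_ed(effect_curve(data.frame(dose = c(20, 44, 80),
#'                                                  effect = c(22.7, 50, 90.9)), "cisplatin"), 50)
#' potency_ratio(ed_nx, ed_cis)
#' @export
potency_ratio <- function(ed_a, ed_b, conf_level = 0.95) {
  if (!inherits(ed_a, "ed_estimate") || !inherits(ed_b, "ed_estimate")) {
    abort("`ed_a` and `ed_b` must be ed_estimate objects.")
  }
  if (!isTRUE(all.equal(ed_a$effect, ed_b$effect))) {
    abort(sprintf("effect levels differ (%g vs %g); potency ratio needs a common level.",
                  ed_a$effect, ed_b$effect))
  }
  ratio <- ed_a$estimate / ed_b$estimate
  ci <- c(NA_real_, NA_real_)
  draws <- NULL
  if (!is.null(ed_a$draws) && !is.null(ed_b$draws) &&
      length(ed_a$draws) == length(ed_b$draws)) {
    pair_ok <- !is.na(ed_a$draws) & !is.na(ed_b$draws)
    draws <- ed_a$draws[pair_ok] / ed_b$draws[pair_ok]
    if (length(draws) >= 2) ci <- percentile_ci(draws, conf_level)
  }
  structure(list(agent_a = ed_a$agent, agent_b = ed_b$agent,
                 effect = ed_a$effect, ratio = ratio,
                 conf_low = ci[1], conf_high = ci[2],
                 conf_level = if (is.na(ci[1])) NA_real_ else conf_level,
                 draws = draws),
            class = "potency_ratio")
}

#' @export
print.potency_ratio <- function(x, ...) {
  cat(sprintf("<potency_ratio> R%g = ED%g(%s)/ED%g(%s) = %.3f",
              x$effect, x$effect, x$agent_a, x$effect, x$agent_b, x$ratio))
  if (!is.na(x$conf_low)) cat(sprintf(" [%.3f, %.3f]", x$conf_low, x$conf_high))
  cat("\n")
  invisible(x)
}

#' Highest effect level common to two curves
#'
#' The largest effect level at which an effective dose exists for both agents
#' without extrapolation: the minimum over the two curves of their maximum
#' mean effect. This is the level at which the maximum-effect potency ratio
#' is evaluated.
#'
#' @param curve_a,curve_b [effect_curve()] objects.
#' @return A single effect level (%).
#' @export
max_common_effect <- function(curve_a, curve_b) {
  check_curve(curve_a, min_points = 1)
  check_curve(curve_b, min_points = 1)
  min(max(curve_a$mean_effect), max(curve_b$mean_effect))
}

#' Likelihood-ratio (G) test of a contingency table
#'
#' `G = 2 * sum(O * ln(O / E))` with expected counts from the table margins,
#' compared to a chi-squared distribution with `(r-1)(c-1)` degrees of
#' freedom (no Williams correction). If any expected count is zero, 0.5 is
#' added to every cell (continuity adjustment) with a message.
#'
#' @param tab A numeric matrix of observed counts (typically 2x2).
#' @return A list with `statistic`, `df`, `p_value`, and the (possibly
#'   adjusted) `observed` table.
#' @examples
#' g_test(matrix(c(30, 10, 10, 30), nrow = 2))
#' @export
g_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab))) abort("counts must be finite and >= 0.")
  if (nrow(tab) < 2 || ncol(tab) < 2) abort("table must be at least 2x2.")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    inform("zero expected cell count; adding 0.5 to every cell (continuity adjustment).")
    tab <- tab + 0.5
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  }
  pos <- tab > 0
  g <- 2 * sum(tab[pos] * log(tab[pos] / expected[pos]))
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = g, df = df,
       p_value = pchisq(g, df, lower.tail = FALSE), observed = tab)
}

#' G-test of potency-ratio constancy across effect levels
#'
#' Tests whether the potency ratio at 50% effect differs consistently from
#' the ratio at the maximum common effect level. Each paired bootstrap draw
#' of each ratio is dichotomized as `> 1` versus `<= 1`; the resulting 2x2
#' table (effect level x category) is submitted to [g_test()]. A
#' non-significant result means the relative potency can be treated as
#' dose-independent, so the additivity isobole may be drawn as a straight
#' line between the two axis intercepts (the Tallarida linearity condition).
#'
#' @param ratio_50 A [potency_ratio()] at E = 50 carrying bootstrap draws.
#' @param ratio_max A [potency_ratio()] at the maximum common effect level,
#'   with draws paired to `ratio_50`.
#' @param alpha Significance threshold for declaring non-constancy.
#' @return A list with the G `statistic`, `p_value`, the contingency
#'   `observed` table, and `linear_isobole` (`TRUE` when `p >= alpha`).
#' @export
constancy_gtest <- function(ratio_50, ratio_max, alpha = 0.05) {
  if (!inherits(ratio_50, "potency_ratio") || !inherits(ratio_max, "potency_ratio")) {
    abort("inputs must be potency_ratio objects.")
  }
  if (is.null(ratio_50$draws) || is.null(ratio_max$draws)) {
    abort("both ratios need bootstrap draws (use bootstrap_ed() upstream).")
  }
  tab <- rbind(
    c(sum(ratio_50$draws > 1), sum(ratio_50$draws <= 1)),
    c(sum(ratio_max$draws > 1), sum(ratio_max$draws <= 1))
  )
  dimnames(tab) <- list(level = c(sprintf("R%g", ratio_50$effect),
                                  sprintf("R%g", ratio_max$effect)),
                        category = c(">1", "<=1"))
  gt <- g_test(tab)
  c(gt, list(linear_isobole = gt$p_value >= alpha, alpha = alpha))
}

#' Loewe interaction index of a dose combination
#'
#' `gamma = a / ED_E(A) + b / ED_E(B)`: the fraction of an additive-equivalent
#' exposure that the combination (a, b) represents at effect level E.
#' `gamma = 1` places the combination exactly on the linear additivity
#' isobole, `gamma < 1` strictly below it (supra-additive territory), and
#' `gamma > 1` above it.
#'
#' @param dose_a,dose_b Combination doses (µM), >= 0.
#' @param ed_a,ed_b Effective doses at the analysis level: positive numbers
#'   or `ed_estimate` objects.
#' @return The interaction index (a single number).
#' @examples
#' interaction_index(10, 20, 51, 44)
#' @export
interaction_index <- function(dose_a, dose_b, ed_a, ed_b) {
  if (inherits(ed_a, "ed_estimate")) ed_a <- ed_a$estimate
  if (inherits(ed_b, "ed_estimate")) ed_b <- ed_b$estimate
  check_number(dose_a, "dose_a", function(v) v >= 0)
  check_number(dose_b, "dose_b", function(v) v >= 0)
  check_number(ed_a, "ed_a", is_positive)
  check_number(ed_b, "ed_b", is_positive)
  dose_a / ed_a + dose_b / ed_b
}

#' Confidence envelope of the additivity isobole
#'
#' For each paired bootstrap resample, the additivity line at effect level E
#' runs from `(ED_E(A), 0)` to `(0, ED_E(B))`; its agent-B axis value at
#' abscissa `a` is `ED_E(B) * (1 - a / ED_E(A))`. The envelope is the
#' pointwise percentile band of that value across resamples, evaluated on a
#' grid of agent-A doses. The central line uses the point estimates. Given
#' the draws, the construction is deterministic. At `a = 0` the band reduces
#' to the marginal percentile CI of `ED_E(B)`.
#'
#' @param ed_a,ed_b `ed_estimate` objects at the same effect level, carrying
#'   paired bootstrap draws (see [bootstrap_ed()]).
#' @param conf_level Band level, default 0.95.
#' @param grid_n Number of grid points along the agent-A axis.
#' @return An `isobole_envelope`: contains a tibble `grid` with columns
#'   `dose_a`, `lower`, `line`, `upper`, plus the draws for exact evaluation
#'   at arbitrary abscissae.
#' @export
isobole_envelope <- function(ed_a, ed_b, conf_level = 0.95, grid_n = 101) {
  if (!inherits(ed_a, "ed_estimate") || !inherits(ed_b, "ed_estimate")) {
    abort("`ed_a` and `ed_b` must be ed_estimate objects.")
  }
  if (!isTRUE(all.equal(ed_a$effect, ed_b$effect))) {
    abort("effect levels of the two ED estimates differ.")
  }
  if (is.null(ed_a$draws) || is.null(ed_b$draws) ||
      length(ed_a$draws) != length(ed_b$draws)) {
    abort("paired bootstrap draws of equal length are required.")
  }
  ok <- !is.na(ed_a$draws) & !is.na(ed_b$draws)
  if (sum(ok) < 2) abort("too few usable paired draws for an envelope.")
  da <- ed_a$draws[ok]
  db <- ed_b$draws[ok]
  a_grid <- seq(0, max(ed_a$estimate, da), length.out = grid_n)
  band <- vapply(a_grid, function(a) {
    percentile_ci(db * (1 - a / da), conf_level)
  }, numeric(2))
  grid <- tibble(dose_a = a_grid,
                 lower = pmax(band[1, ], 0),
                 line = pmax(ed_b$estimate * (1 - a_grid / ed_a$estimate), 0),
                 upper = pmax(band[2, ], 0))
  structure(list(grid = grid, effect = ed_a$effect,
                 agent_a = ed_a$agent, agent_b = ed_b$agent,
                 ed_a = ed_a$estimate, ed_b = ed_b$estimate,
                 draws_a = da, draws_b = db, conf_level = conf_level),
            class = "isobole_envelope")
}

# envelope bounds (B axis) at an arbitrary agent-A abscissa, from the draws
envelope_at <- function(env, dose_a) {
  ci <- percentile_ci(env$draws_b * (1 - dose_a / env$draws_a), env$conf_level)
  c(lower = ci[1], upper = ci[2],
    line = env$ed_b * (1 - dose_a / env$ed_a))
}

#' @export
print.isobole_envelope <- function(x, ...) {
  cat(sprintf("<isobole_envelope> E = %g%%: %s intercept %.3g uM, %s intercept %.3g uM, %g%% band (%d draws)\n",
              x$effect, x$agent_a, x$ed_a, x$agent_b, x$ed_b,
              100 * x$conf_level, length(x$draws_a)))
  invisible(x)
}

#' Classify a dose combination against the additivity isobole
#'
#' Places the combination point `(dose_a, dose_b)` relative to the additivity
#' line and its confidence envelope at the envelope's effect level:
#' * `synergistic` - strictly below the lower envelope;
#' * `antagonistic-consistent` - strictly above the upper envelope;
#' * `inconclusive` - interaction index < 1 (below the line) but inside the
#'   envelope, so supra-additivity cannot be concluded;
#' * `additive-consistent` - inside the envelope and on/above the line.
#'
#' @param envelope An [isobole_envelope()].
#' @param dose_a,dose_b The combination doses (µM).
#' @return A list with `verdict`, `gamma` (interaction index), and the
#'   envelope `lower`, `line`, `upper` values at `dose_a`.
#' @export
classify_combination <- function(envelope, dose_a, dose_b) {
  if (!inherits(envelope, "isobole_envelope")) {
    abort("`envelope` must be an isobole_envelope.")
  }
  check_number(dose_a, "dose_a", function(v) v >= 0)
  check_number(dose_b, "dose_b", function(v) v >= 0)
  at <- envelope_at(envelope, dose_a)
  gamma <- interaction_index(dose_a, dose_b, envelope$ed_a, envelope$ed_b)
  verdict <- if (dose_b < at[["lower"]]) "synergistic"
             else if (dose_b > at[["upper"]]) "antagonistic-consistent"
             else if (gamma < 1) "inconclusive"
             else "additive-consistent"
  list(verdict = verdict, gamma = gamma,
       lower = at[["lower"]], line = at[["line"]], upper = at[["upper"]],
       effect = envelope$effect)
}

#' Choose the isobolographic analysis effect level
#'
#' The default analysis level is E = 50. When the observed combination
#' effect is significantly different from 50% (one-sample t-test of the
#' replicate effects against 50) and its mean exceeds 50%, the analysis is
#' escalated to the observed level, `E* = floor(mean effect)` - comparing a
#' high-effect combination against the 50% isobole would be meaningless.
#'
#' @param combo A [combination_observation()] or a numeric vector of
#'   replicate effects (n >= 2).
#' @param alpha Significance threshold, default 0.05.
#' @return An `escalation_decision` with the t `statistic`, `p_value`, and
#'   the chosen `level`.
#' @examples
#' escalate_effect_level(c(84, 77, 92))
#' @export
escalate_effect_level <- function(combo, alpha = 0.05) {
  effects <- if (inherits(combo, "combo_obs")) combo$effects else combo
  if (!is.numeric(effects) || length(effects) < 2) {
    abort("need >= 2 replicate combination effects (no variance estimate otherwise).")
  }
  m <- mean(effects)
  s <- sd(effects)
  n <- length(effects)
  if (s == 0) {
    stat <- if (m == 50) 0 else sign(m - 50) * Inf
    p <- if (m == 50) 1 else 0
  } else {
    tt <- t.test(effects, mu = 50)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  level <- if (p < alpha && m > 50) floor(m) else 50
  structure(list(mean = m, se = if (n >= 2) s / sqrt(n) else NA_real_, n = n,
                 statistic = stat, p_value = p, alpha = alpha,
                 level = level),
            class = "escalation_decision")
}

#' @export
print.escalation_decision <- function(x, ...) {
  cat(sprintf("<escalation_decision> combination effect %.1f%% +/- %.1f (n = %d): t = %.2f vs 50, p = %.3g -> analyze at E = %g%%\n",
              x$mean, x$se, x$n, x$statistic, x$p_value, x$level))
  invisible(x)
}
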