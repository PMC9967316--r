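#' Two-stage isobolographic synergy assessment
#'
#' Runs the full Loewe-additivity analysis of a two-agent combination:
#'
#' 1. linear F-test screen of both single-agent dose-effect curves (a
#'    non-significant screen warns but does not stop the analysis);
#' 2. effect-level escalation: if the observed combination effect is
#'    significantly above 50%, the analysis level is raised to
#'    `E* = floor(mean effect)`, capped at the highest effect level both
#'    curves reach (interpolation never extrapolates);
#' 3. paired within-dose bootstrap of the effective doses of both agents at
#'    E = 50, at E*, and at the maximum common effect level;
#' 4. potency ratios R50 and R_max with a G-test of their constancy - a
#'    non-significant G-test licenses the linear additivity isobole;
#' 5. confidence envelopes of the isobole at each analysis level and
#'    classification of the combination point (interaction index, verdict).
#'
#' The returned object reports the assessment at E = 50 and, when escalation
#' occurred, at E*; the headline `verdict` is the one at the escalated level.
#'
#' @param curve_a,curve_b [effect_curve()] objects for the two agents
#'   (combination doses `dose_a` of agent A, `dose_b` of agent B).
#' @param combo A [combination_observation()] for the combination condition.
#' @param B Bootstrap resamples, default 2000.
#' @param seed Integer seed for the bootstrap (`NULL`: current RNG stream).
#' @param conf_level Level of CIs and isobole envelopes, default 0.95.
#' @param alpha Significance threshold for the escalation t-test and the
#'   constancy G-test.
#' @return A `synergy_assessment`; supports [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' viab <- normalize_viability(simulate_plate(assay_truth(seed = 7)))
#' a <- build_effect_curve(viab, "naloxone")
#' b <- build_effect_curve(viab, "cisplatin")
#' combo <- combination_observation(viab, "naloxone", "cisplatin", 10, 20)
#' fit <- assess_synergy(a, b, combo, B = 500, seed = 7)
#' fit
#' @export
assess_synergy <- function(curve_a, curve_b, combo, B = 2000, seed = NULL,
                           conf_level = 0.95, alpha = 0.05) {
  check_curve(curve_a)
  check_curve(curve_b)
  if (!inherits(combo, "combo_obs")) {
    abort("`combo` must be a combination_observation().")
  }
  agent_a <- attr(curve_a, "agent")
  agent_b <- attr(curve_b, "agent")

  for (cv in list(curve_a, curve_b)) {
    screen <- fit_linear(cv)
    if (screen$p_value >= 0.05) {
      warn(sprintf("linear screen for '%s' not significant (F = %.3g, p = %.3g); dose-effect relation is weak.",
                   attr(cv, "agent"), screen$statistic, screen$p_value))
    }
  }

  e_max <- max_common_effect(curve_a, curve_b)
  if (50 > e_max) {
    abort(sprintf("maximum common effect is %.3g%% (< 50%%); isobolographic analysis at E = 50 impossible.",
                  e_max))
  }
  escalation <- escalate_effect_level(combo, alpha = alpha)
  e_star <- min(escalation$level, floor(e_max))
  if (e_star < escalation$level) {
    warn(sprintf("escalated level %g%% exceeds the maximum common effect %.3g%%; capped at %g%%.",
                 escalation$level, e_max, e_star))
  }
  levels_ed <- unique(c(50, e_star))
  levels_all <- unique(c(levels_ed, e_max))

  draws <- with_seed_maybe(seed, {
    list(a = boot_ed_draws(curve_a, levels_all, B),
         b = boot_ed_draws(curve_b, levels_all, B))
  })

  ed_of <- function(curve, dr, level, strict) {
    est <- interpolate_ed(curve, level)
    v <- dr[, as.character(level)]
    n_unreach <- sum(is.na(v))
    if (strict && n_unreach > B / 2) {
      abort(sprintf("bootstrap CI unreliable at E = %g%% for '%s': %d/%d resamples unreachable.",
                    level, est$agent, n_unreach, B))
    }
    ok <- v[!is.na(v)]
    ci <- if (length(ok) >= 2) percentile_ci(ok, conf_level) else c(NA_real_, NA_real_)
    new_ed_estimate(est$agent, level, est$estimate, ci[1], ci[2], conf_level,
                    as.integer(B), as.integer(n_unreach), draws = v)
  }

  ed_a <- lapply(levels_ed, function(e) ed_of(curve_a, draws$a, e, strict = TRUE))
  ed_b <- lapply(levels_ed, function(e) ed_of(curve_b, draws$b, e, strict = TRUE))
  names(ed_a) <- names(ed_b) <- as.character(levels_ed)

  r50 <- potency_ratio(ed_a[["50"]], ed_b[["50"]], conf_level)
  ed_a_max <- ed_of(curve_a, draws$a, e_max, strict = FALSE)
  ed_b_max <- ed_of(curve_b, draws$b, e_max, strict = FALSE)
  r_max <- potency_ratio(ed_a_max, ed_b_max, conf_level)
  constancy <- constancy_gtest(r50, r_max, alpha = alpha)

  env <- lapply(as.character(levels_ed), function(e) {
    isobole_envelope(ed_a[[e]], ed_b[[e]], conf_level)
  })
  names(env) <- as.character(levels_ed)

  rows <- lapply(as.character(levels_ed), function(e) {
    cls <- classify_combination(env[[e]], combo$dose_a, combo$dose_b)
    tibble(effect = as.numeric(e),
           ed_a = ed_a[[e]]$estimate, ed_b = ed_b[[e]]$estimate,
           gamma = cls$gamma, env_lower = cls$lower, env_line = cls$line,
           env_upper = cls$upper, verdict = cls$verdict)
  })
  levels_tbl <- dplyr::bind_rows(rows)

  structure(list(agents = c(a = agent_a, b = agent_b),
                 combo_dose = c(a = combo$dose_a, b = combo$dose_b),
                 combo = combo,
                 escalation = escalation,
                 analysis_level = e_star,
                 r50 = r50, r_max = r_max, constancy = constancy,
                 ed_a = ed_a, ed_b = ed_b,
                 envelopes = env,
                 levels = levels_tbl,
                 verdict = levels_tbl$verdict[levels_tbl$effect == e_star],
                 B = as.integer(B), conf_level = conf_level, seed = seed),
            class = "synergy_assessment")
}

#' @export
print.synergy_assessment <- function(x, ...) {
  cat(sprintf("<synergy_assessment> %s + %s at (%g, %g) uM\n",
              x$agents["a"], x$agents["b"], x$combo_dose["a"], x$combo_dose["b"]))
  cat(sprintf("  combination effect: %.1f%% +/- %.1f (SE), n = %d\n",
              x$combo$mean, x$combo$se, x$combo$n))
  cat(sprintf("  escalation: t = %.2f vs 50%%, p = %.3g -> analysis level E = %g%%\n",
              x$escalation$statistic, x$escalation$p_value, x$analysis_level))
  cat(sprintf("  potency ratio: R50 = %.3f, R%g = %.3f; constancy G = %.3g, p = %.3g (%s isobole)\n",
              x$r50$ratio, x$r_max$effect, x$r_max$ratio,
              x$constancy$statistic, x$constancy$p_value,
              if (x$constancy$linear_isobole) "linear" else "non-linear"))
  for (i in seq_len(nrow(x$levels))) {
    with(x$levels[i, ], cat(sprintf(
      "  E = %g%%: intercepts (%.3g, %.3g) uM, gamma = %.3f, envelope [%.3g, %.3g] -> %s\n",
      effect, ed_a, ed_b, gamma, env_lower, env_upper, verdict)))
  }
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}
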