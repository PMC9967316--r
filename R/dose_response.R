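# Dose-response screening and effective-dose interpolation.
#
# The interpolant is the shape-preserving (monotonicity-preserving) piecewise
# cubic Hermite of Fritsch & Carlson, anchored at (0, 0). On 3-8-point
# viability curves it reproduces every node exactly and introduces no values
# outside the range of neighboring node effects, so no spurious ED roots can
# appear on monotone data.

# smallest dose at which the interpolant through (doses, means) reaches each
# effect level in `levels`; NA where the level exceeds the observed maximum.
# Caller guarantees doses strictly increasing and >= 0.
ed_point_multi <- function(doses, means, levels, tol = NULL) {
  if (doses[1] > 0) {
    doses <- c(0, doses)
    means <- c(0, means)
  }
  tol <- tol %||% max(doses) * 1e-10
  k <- length(doses)
  sf <- NULL
  out <- rep(NA_real_, length(levels))
  for (j in seq_along(levels)) {
    e <- levels[j]
    if (e > max(means)) next
    for (i in seq_len(k)) {
      if (means[i] == e) { out[j] <- doses[i]; break }
      if (i < k && (means[i] - e) * (means[i + 1] - e) < 0) {
        if (is.null(sf)) sf <- splinefun(doses, means, method = "monoH.FC")
        out[j] <- uniroot(function(x) sf(x) - e,
                          lower = doses[i], upper = doses[i + 1],
                          tol = tol)$root
        break
      }
    }
  }
  out
}

new_ed_estimate <- function(agent, effect, estimate, conf_low = NA_real_,
                            conf_high = NA_real_, conf_level = NA_real_,
                            B = NA_integer_, n_unreachable = NA_integer_,
                            draws = NULL) {
  structure(list(agent = agent, effect = effect, estimate = estimate,
                 conf_low = conf_low, conf_high = conf_high,
                 conf_level = conf_level, B = B,
                 n_unreachable = n_unreachable,
                 method = "monotone piecewise cubic", draws = draws),
            class = "ed_estimate")
}

#' @export
print.ed_estimate <- function(x, ...) {
  cat(sprintf("<ed_estimate> %s: ED%g = %.3g uM", x$agent, x$effect, x$estimate))
  if (!is.na(x$conf_low)) {
    cat(sprintf(" [%.3g, %.3g] (%g%% percentile bootstrap, B = %d)",
                x$conf_low, x$conf_high, 100 * x$conf_level, x$B))
  }
  cat("\n")
  invisible(x)
}

check_curve <- function(curve, min_points = 3) {
  if (!inherits(curve, "effect_curve")) abort("`curve` must be an effect_curve.")
  if (nrow(curve) < min_points) {
    abort(sprintf("curve needs >= %d dose points (has %d).", min_points, nrow(curve)))
  }
}

#' Linear screen of a dose-effect curve
#'
#' Ordinary least squares of the per-dose mean effect on dose, with the
#' F-test of the regression. This is a significance screen applied before
#' effective-dose interpolation - it asks only whether effect grows with dose,
#' and is not the model from which EDs are taken (those come from
#' [interpolate_ed()]).
#'
#' @param curve An [effect_curve()].
#' @return A `dose_linfit`: slope (%/µM), intercept (%), F statistic, p-value,
#'   R-squared, and number of dose points; supports [tidy()] and [glance()].
#' @examples
#' curve <- effect_curve(data.frame(dose = rep(c(10, 20, 40), each = 3),
#'                                  effect = rep(c(12, 25, 49), each = 3) + rnorm(9)))
#' glance(fit_linear(curve))
#' @export
fit_linear <- function(curve) {
  check_curve(curve)
  if (length(unique(curve$dose)) < 2) abort("all doses identical; cannot fit a line.")
  x <- curve$dose
  y <- curve$mean_effect
  fit <- lm(y ~ x)
  n <- length(x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(fit$residuals^2)
  ss_reg <- max(ss_tot - ss_res, 0)
  f_stat <- if (ss_reg == 0) 0
            else if (ss_res == 0) Inf
            else (ss_reg / 1) / (ss_res / (n - 2))
  p <- pf(f_stat, 1, n - 2, lower.tail = FALSE)
  structure(list(agent = attr(curve, "agent"),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 statistic = f_stat, p_value = p,
                 r_squared = if (ss_tot == 0) 0 else ss_reg / ss_tot,
                 n = n),
            class = "dose_linfit")
}

#' @export
print.dose_linfit <- function(x, ...) {
  cat(sprintf("<dose_linfit> %s: effect = %.3g + %.3g * dose (R^2 = %.3f, F = %.3g, p = %.3g)\n",
              x$agent, x$intercept, x$slope, x$r_squared, x$statistic, x$p_value))
  invisible(x)
}

#' Interpolate the effective dose at an effect level
#'
#' Finds `ED_E`, the smallest dose at which the shape-preserving piecewise
#' cubic interpolant through the per-dose mean effects (anchored at the
#' origin) reaches effect level `E`. The interpolant reproduces its nodes
#' exactly; when the curve crosses `E` more than once, the first (smallest)
#' crossing is returned. Effect levels above the maximum observed mean effect
#' are an error: the method interpolates and never extrapolates beyond the
#' largest tested dose.
#'
#' @param curve An [effect_curve()] with at least 3 dose points.
#' @param effect Effect level E (%), `0 < E <= max(mean effect)`.
#' @return An `ed_estimate` (point estimate only; see [bootstrap_ed()] for
#'   confidence intervals).
#' @examples
#' curve <- effect_curve(data.frame(dose = c(50, 75, 100), effect = c(50, 75, 100)))
#' interpolate_ed(curve, 50)$estimate
#' @export
interpolate_ed <- function(curve, effect) {
  check_curve(curve)
  check_number(effect, "effect", is_positive)
  mx <- max(curve$mean_effect)
  if (effect > mx) {
    abort(sprintf("effect level %g%% unreachable: maximum observed mean effect is %.3g%% (no extrapolation).",
                  effect, mx))
  }
  est <- ed_point_multi(curve$dose, curve$mean_effect, effect)
  if (is.na(est)) {
    abort(sprintf("no crossing of effect level %g%% found on the curve.", effect))
  }
  new_ed_estimate(attr(curve, "agent"), effect, est)
}

# B bootstrap resamples of per-dose replicate effects -> matrix of ED draws
# (B x length(levels)); NA where the resampled curve does not reach the level.
# Uses the current RNG stream.
boot_ed_draws <- function(curve, levels, B) {
  doses <- curve$dose
  nd <- length(doses)
  mean_mat <- matrix(NA_real_, nrow = B, ncol = nd)
  for (d in seq_len(nd)) {
    eff <- curve$effects[[d]]
    n <- length(eff)
    idx <- sample.int(n, n * B, replace = TRUE)
    mean_mat[, d] <- colMeans(matrix(eff[idx], nrow = n, ncol = B))
  }
  draws <- matrix(NA_real_, nrow = B, ncol = length(levels))
  for (b in seq_len(B)) {
    draws[b, ] <- ed_point_multi(doses, mean_mat[b, ], levels)
  }
  colnames(draws) <- as.character(levels)
  draws
}

#' Bootstrap confidence interval for an effective dose
#'
#' Nonparametric bootstrap of [interpolate_ed()]: replicate effects are
#' resampled with replacement within each dose, the interpolant is refitted,
#' and `ED_E` recomputed for each of `B` resamples; the confidence interval
#' is the percentile interval of the resampled EDs. Resamples whose curve
#' does not reach `E` are dropped and counted (`n_unreachable`); if more than
#' half of the resamples are unreachable the interval is declared unreliable
#' and an error is raised. Given a seed the result is fully deterministic.
#'
#' @inheritParams interpolate_ed
#' @param B Number of bootstrap resamples (>= 200).
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @param conf_level Confidence level, default 0.95.
#' @return An `ed_estimate` with `conf_low`/`conf_high` and the vector of
#'   bootstrap draws attached (for downstream pairing).
#' @examples
#' curve <- effect_curve(data.frame(dose = rep(c(10, 30, 50), each = 4),
#'                                  effect = c(11, 14, 9, 12, 32, 28, 35, 30, 52, 47, 55, 50)))
#' bootstrap_ed(curve, 30, B = 500, seed = 1)
#' @export
bootstrap_ed <- function(curve, effect, B = 2000, seed = NULL, conf_level = 0.95) {
  est <- interpolate_ed(curve, effect)
  check_number(B, "B", function(v) v >= 200 && v == round(v))
  check_number(conf_level, "conf_level", function(v) v > 0 && v < 1)
  if (any(curve$n < 2)) {
    abort("bootstrap requires >= 2 replicates at every dose.")
  }
  draws <- with_seed_maybe(seed, boot_ed_draws(curve, effect, B))[, 1]
  n_unreach <- sum(is.na(draws))
  if (n_unreach > B / 2) {
    abort(sprintf(paste0("bootstrap CI unreliable: %d of %d resamples (%.0f%%) do not reach ",
                         "effect level %g%%; collect data at higher doses or lower E."),
                  n_unreach, B, 100 * n_unreach / B, effect))
  }
  ok <- draws[!is.na(draws)]
  ci <- percentile_ci(ok, conf_level)
  if (!(ci[1] <= est$estimate && est$estimate <= ci[2])) {
    inform(sprintf("percentile CI [%.3g, %.3g] does not bracket the point estimate %.3g (agent '%s', E = %g).",
                   ci[1], ci[2], est$estimate, est$agent, effect))
  }
  new_ed_estimate(est$agent, effect, est$estimate,
                  conf_low = ci[1], conf_high = ci[2],
                  conf_level = conf_level, B = as.integer(B),
                  n_unreachable = as.integer(n_unreach), draws = draws)
}
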