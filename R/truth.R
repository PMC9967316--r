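#' Linear dose-effect ground truth
#'
#' Convenience constructor for a dose-effect function of the form
#' `E(d) = min(emax, 50 * d / ed50)`: linear through the origin, calibrated so
#' that the dose `ed50` produces a 50% effect, and saturating at `emax`.
#' Useful as a near-linear single-agent ground truth for simulations.
#'
#' @param ed50 Dose (µM) at which the true effect is 50%.
#' @param emax Saturation effect (%), default 100.
#' @return A function mapping dose (µM) to true effect (%).
#' @examples
#' f <- linear_effect(44)
#' f(c(0, 22, 44, 100))
#' @export
linear_effect <- function(ed50, emax = 100) {
  check_number(ed50, "ed50", is_positive)
  check_number(emax, "emax", is_positive)
  force(ed50); force(emax)
  function(dose) pmin(emax, 50 * dose / ed50)
}

#' Ground truth for a simulated viability plate assay
#'
#' Defines the conditions from which [simulate_plate()] draws: per-agent true
#' dose-effect functions on their dose grids, a two-agent combination with its
#' true effect, the replicate count per condition, and the noise model
#' (additive Gaussian, in percentage points of viability). Defaults emulate a
#' cisplatin + naloxone cytotoxicity experiment in head-and-neck cancer cells:
#' near-linear single-agent curves with ED50s of 51 µM (naloxone) and 44 µM
#' (cisplatin), a supra-additive combination (naloxone 10 µM + cisplatin 20 µM,
#' true effect 85%), three replicate wells per condition, and sigma = 8
#' percentage points of well-to-well noise.
#'
#' The default dose grids keep the low-dose gradient of such experiments
#' (naloxone from 0.1 µM, cisplatin from 5 µM) and extend both agents to
#' 100 µM so that both the 50% and the escalated (~84%) effect levels lie
#' inside the tested range and every effective dose is obtained by
#' interpolation, never extrapolation.
#'
#' @param agents Named list; one entry per agent, each a list with elements
#'   `effect` (function: dose -> true effect %) and `doses` (numeric vector of
#'   nonzero doses, µM).
#' @param combo List with `agent_a`, `dose_a`, `agent_b`, `dose_b`, `effect`
#'   (the true combination effect, %). Set to `NULL` for no combination wells.
#' @param n Replicate wells per condition (>= 2).
#' @param sigma Additive Gaussian noise SD on viability, percentage points.
#' @param control_mean Mean control-well absorbance (OD450).
#' @param control_cv Coefficient of variation of control-well absorbance.
#' @param n_control Number of control wells per plate.
#' @param seed Default random seed used by [simulate_plate()].
#' @return An object of class `assay_truth`.
#' @seealso [simulate_plate()], [linear_effect()]
#' @examples
#' truth <- assay_truth(seed = 1)
#' truth
#' @export
assay_truth <- function(agents = list(
                          naloxone  = list(effect = linear_effect(51),
                                           doses = c(0.1, 1, 10, 20, 40, 60, 80, 100)),
                          cisplatin = list(effect = linear_effect(44),
                                           doses = c(5, 10, 20, 25, 40, 60, 80, 100))),
                        combo = list(agent_a = "naloxone", dose_a = 10,
                                     agent_b = "cisplatin", dose_b = 20,
                                     effect = 85),
                        n = 3,
                        sigma = 8,
                        control_mean = 1,
                        control_cv = 0.05,
                        n_control = 6,
                        seed = NULL) {
  if (!is.list(agents) || length(agents) == 0 || is.null(names(agents)) ||
      any(!nzchar(names(agents)))) {
    abort("`agents` must be a non-empty named list.")
  }
  for (nm in names(agents)) {
    ag <- agents[[nm]]
    if (!is.function(ag$effect) || !is.numeric(ag$doses) || length(ag$doses) < 1) {
      abort(sprintf("agent '%s' needs an `effect` function and numeric `doses`.", nm))
    }
    if (any(ag$doses < 0)) abort(sprintf("agent '%s' has a negative dose.", nm))
    f0 <- ag$effect(0)
    if (abs(f0) > 1e-8) {
      abort(sprintf("agent '%s': effect function must satisfy f(0) = 0 (got %g).", nm, f0))
    }
    grid <- sort(unique(c(0, ag$doses,
                          seq(0, max(ag$doses), length.out = 201))))
    fe <- ag$effect(grid)
    if (any(diff(fe) < -1e-8)) {
      abort(sprintf("agent '%s': effect function is not non-decreasing on its dose range.", nm))
    }
    agents[[nm]]$doses <- sort(unique(ag$doses))
  }
  if (!is.null(combo)) {
    need <- c("agent_a", "dose_a", "agent_b", "dose_b", "effect")
    if (!all(need %in% names(combo))) {
      abort("`combo` must have agent_a, dose_a, agent_b, dose_b, effect.")
    }
    if (!all(c(combo$agent_a, combo$agent_b) %in% names(agents))) {
      abort("`combo` agents must appear in `agents`.")
    }
    check_number(combo$dose_a, "combo$dose_a", function(v) v >= 0)
    check_number(combo$dose_b, "combo$dose_b", function(v) v >= 0)
    check_number(combo$effect, "combo$effect")
  }
  check_number(n, "n", function(v) v >= 2 && v == round(v))
  check_number(sigma, "sigma", function(v) v >= 0)
  check_number(control_mean, "control_mean", is_positive)
  check_number(control_cv, "control_cv", function(v) v >= 0)
  check_number(n_control, "n_control", function(v) v >= 1 && v == round(v))

  structure(list(agents = agents, combo = combo, n = as.integer(n),
                 sigma = sigma, control_mean = control_mean,
                 control_cv = control_cv, n_control = as.integer(n_control),
                 seed = seed),
            class = "assay_truth")
}

#' @export
print.assay_truth <- function(x, ...) {
  cat("<assay_truth>\n")
  for (nm in names(x$agents)) {
    cat(sprintf("  %s: %d doses in [%g, %g] uM\n", nm,
                length(x$agents[[nm]]$doses), min(x$agents[[nm]]$doses),
                max(x$agents[[nm]]$doses)))
  }
  if (!is.null(x$combo)) {
    cat(sprintf("  combo: %s %g uM + %s %g uM, true effect %g%%\n",
                x$combo$agent_a, x$combo$dose_a, x$combo$agent_b,
                x$combo$dose_b, x$combo$effect))
  }
  cat(sprintf("  n = %d replicates/condition, sigma = %g pp, %d control wells\n",
              x$n, x$sigma, x$n_control))
  invisible(x)
}

#' Ground truth for simulated xenograft tumor growth
#'
#' Defines the conditions from which [simulate_growth()] draws: exponential
#' tumor growth `V(t) = V0 * exp(rate * t)` per animal with group-specific
#' daily growth rates, log-normal between-animal baseline variation, and
#' log-normal measurement noise applied to the caliper length and width that
#' encode each volume (`V = L * W^2 / 2`). Defaults emulate a four-arm
#' mouse experiment (control, naloxone, cisplatin, cisplatin + naloxone):
#' 30 animals, treatment started at a 100 mm^3 average baseline, caliper
#' measurements twice a week for six weeks, and growth rates calibrated so
#' that at the final day naloxone reduces mean volume ~37% vs control and
#' adding naloxone to cisplatin reduces it a further ~64% vs cisplatin alone.
#'
#' @param baseline Baseline tumor volume (mm^3) at day 0.
#' @param rates Named numeric vector of daily exponential growth rates, one
#'   per treatment group.
#' @param n_per_group Animals per group; scalar or vector matching `rates`.
#' @param days Measurement days (integers >= 0).
#' @param noise_cv CV of the multiplicative measurement noise on each caliper
#'   dimension.
#' @param baseline_cv CV of the between-animal baseline volume.
#' @param aspect Tumor aspect ratio length/width used to encode volumes as
#'   caliper pairs (>= 1).
#' @param seed Default random seed used by [simulate_growth()].
#' @return An object of class `growth_truth`.
#' @seealso [simulate_growth()], [tumor_volume()]
#' @export
growth_truth <- function(baseline = 100,
                         rates = c(control = log(15) / 42,
                                   naloxone = log(15) / 42 + log(0.63) / 42,
                                   cisplatin = log(15) / 42 + log(0.5) / 42,
                                   "cisplatin+naloxone" =
                                     log(15) / 42 + log(0.5) / 42 + log(0.36) / 42),
                         n_per_group = c(8, 8, 7, 7),
                         days = c(0, 3, 7, 10, 14, 17, 21, 24, 28, 31, 35, 38, 42),
                         noise_cv = 0.05,
                         baseline_cv = 0.2,
                         aspect = 1.5,
                         seed = NULL) {
  check_number(baseline, "baseline", is_positive)
  if (!is.numeric(rates) || length(rates) < 1 || is.null(names(rates)) ||
      any(!is.finite(rates))) {
    abort("`rates` must be a named numeric vector of finite growth rates.")
  }
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, length(rates))
  if (length(n_per_group) != length(rates) || any(n_per_group < 1)) {
    abort("`n_per_group` must give >= 1 animal for every group.")
  }
  if (!is.numeric(days) || any(days < 0) || anyDuplicated(days)) {
    abort("`days` must be distinct non-negative numbers.")
  }
  check_number(noise_cv, "noise_cv", function(v) v >= 0)
  check_number(baseline_cv, "baseline_cv", function(v) v >= 0)
  check_number(aspect, "aspect", function(v) v >= 1)

  structure(list(baseline = baseline, rates = rates,
                 n_per_group = as.integer(n_per_group),
                 days = sort(days), noise_cv = noise_cv,
                 baseline_cv = baseline_cv, aspect = aspect, seed = seed),
            class = "growth_truth")
}

#' @export
print.growth_truth <- function(x, ...) {
  cat("<growth_truth>\n")
  cat(sprintf("  baseline %g mm^3, %d groups, %d animals, days %g..%g\n",
              x$baseline, length(x$rates), sum(x$n_per_group),
              min(x$days), max(x$days)))
  for (i in seq_along(x$rates)) {
    cat(sprintf("  %s: rate %.4f/day, n = %d\n", names(x$rates)[i],
                x$rates[i], x$n_per_group[i]))
  }
  invisible(x)
}
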