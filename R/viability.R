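#' Normalize raw absorbances to viability and effect
#'
#' Converts OD450 readings to percent viability relative to the untreated
#' control wells of the same plate:
#' `viability = 100 * absorbance / mean(control absorbance)`, and
#' `effect = 100 - viability` (percent reduction in viability). Values are
#' deliberately not clamped: a proliferation-promoting treatment yields a
#' negative effect. Normalization is per plate, so a constant scaling of all
#' absorbances on a plate (gain, path length) cancels.
#'
#' @param wells A tibble of well records ([simulate_plate()] /
#'   [read_plate_csv()]).
#' @return The input tibble with `viability` and `effect` columns appended.
#' @examples
#' plate <- simulate_plate(assay_truth(seed = 1))
#' head(normalize_viability(plate))
#' @export
normalize_viability <- function(wells) {
  check_columns(wells, plate_cols, "wells")
  if (any(!is.finite(wells$absorbance) | wells$absorbance <= 0)) {
    abort("absorbances must be finite and > 0.")
  }
  ctrl <- dplyr::filter(wells, .data$is_control)
  if (nrow(ctrl) == 0) abort("no control wells present.")
  ctrl_means <- dplyr::summarise(dplyr::group_by(ctrl, .data$plate_id),
                                 .ctrl_mean = mean(.data$absorbance),
                                 .groups = "drop")
  missing <- setdiff(unique(wells$plate_id), ctrl_means$plate_id)
  if (length(missing)) {
    abort(sprintf("plate(s) without control wells: %s.",
                  paste(missing, collapse = ", ")))
  }
  if (any(ctrl_means$.ctrl_mean <= 0)) abort("control mean absorbance must be > 0.")
  out <- dplyr::left_join(wells, ctrl_means, by = "plate_id")
  out <- dplyr::mutate(out,
                       viability = 100 * .data$absorbance / .data$.ctrl_mean,
                       effect = 100 - .data$viability)
  dplyr::select(out, -".ctrl_mean")
}

new_effect_curve <- function(tbl, agent) {
  structure(tbl, agent = agent,
            class = c("effect_curve", class(tibble())))
}

#' Build a per-agent dose-effect curve
#'
#' Aggregates replicate-level effects into an ordered dose-effect curve:
#' doses sorted ascending (duplicate dose rows merged), replicate effects
#' kept per dose, and per-dose mean and standard error
#' (`SE = sd / sqrt(n)`) computed. A dose with a single replicate keeps its
#' mean but gets `NA` SE, with a warning. The result is invariant to the
#' ordering of the input rows.
#'
#' @param data For `effect_curve()`: a data frame with columns `dose` and
#'   `effect`, one row per replicate well. For `build_effect_curve()`: a
#'   normalized well table from [normalize_viability()].
#' @param agent Agent name; for `build_effect_curve()` this selects the
#'   single-agent wells (the agent present alone, at nonzero dose).
#' @return An `effect_curve`: a tibble with columns `dose`, `effects`
#'   (list of replicate effects), `mean_effect`, `se`, `n`, and an `agent`
#'   attribute.
#' @examples
#' viab <- normalize_viability(simulate_plate(assay_truth(seed = 1)))
#' build_effect_curve(viab, "cisplatin")
#' @export
effect_curve <- function(data, agent = "agent") {
  if (!all(c("dose", "effect") %in% names(data))) {
    abort("`data` must have columns `dose` and `effect`.")
  }
  if (nrow(data) == 0) abort("no effect observations supplied.")
  if (any(data$dose < 0)) abort("doses must be >= 0.")
  # replicate effects are stored sorted: the curve is a per-dose multiset,
  # invariant to input row order and replicate relabeling
  tbl <- dplyr::summarise(dplyr::group_by(as_tibble(data), .data$dose),
                          effects = list(sort(.data$effect)),
                          mean_effect = mean(.data$effect),
                          n = dplyr::n(),
                          .groups = "drop")
  tbl <- dplyr::arrange(tbl, .data$dose)
  tbl$se <- purrr::map_dbl(tbl$effects,
                           function(e) if (length(e) >= 2) sd(e) / sqrt(length(e)) else NA_real_)
  if (any(tbl$n < 2)) {
    warn(sprintf("agent '%s': %d dose(s) with a single replicate; SE omitted there.",
                 agent, sum(tbl$n < 2)))
  }
  new_effect_curve(tbl[c("dose", "effects", "mean_effect", "se", "n")], agent)
}

#' @rdname effect_curve
#' @export
build_effect_curve <- function(data, agent) {
  if (!"effect" %in% names(data)) abort("`data` must be normalized (see normalize_viability()).")
  single <- dplyr::filter(
    data,
    (!is.na(.data$agent1) & .data$agent1 == agent & .data$dose1 > 0 &
       (is.na(.data$agent2) | .data$dose2 == 0)) |
      (!is.na(.data$agent2) & .data$agent2 == agent & .data$dose2 > 0 &
         (is.na(.data$agent1) | .data$dose1 == 0))
  )
  if (nrow(single) == 0) abort(sprintf("no single-agent wells found for '%s'.", agent))
  single$dose <- ifelse(!is.na(single$agent1) & single$agent1 == agent,
                        single$dose1, single$dose2)
  effect_curve(single[c("dose", "effect")], agent)
}

#' @export
print.effect_curve <- function(x, ...) {
  cat(sprintf("<effect_curve> agent '%s', %d doses\n", attr(x, "agent"), nrow(x)))
  NextMethod()
}

#' Summarize a two-agent combination condition
#'
#' Extracts the replicate effects of the wells treated with both agents at
#' the given dose pair and summarizes them (mean, SE, n).
#'
#' @param data A normalized well table from [normalize_viability()], or a
#'   numeric vector of replicate effects.
#' @param agent_a,agent_b Agent names (either order matches the wells).
#' @param dose_a,dose_b Doses (µM) of `agent_a` and `agent_b`.
#' @return A `combo_obs` object: dose pair, replicate effects, mean, SE, n.
#' @examples
#' viab <- normalize_viability(simulate_plate(assay_truth(seed = 1)))
#' combination_observation(viab, "naloxone", "cisplatin", 10, 20)
#' @export
combination_observation <- function(data, agent_a, agent_b, dose_a, dose_b) {
  if (is.numeric(data)) {
    effects <- data
  } else {
    if (!"effect" %in% names(data)) abort("`data` must be normalized (see normalize_viability()).")
    m <- dplyr::filter(
      data,
      (!is.na(.data$agent1) & !is.na(.data$agent2)) &
        ((.data$agent1 == agent_a & .data$dose1 == dose_a &
            .data$agent2 == agent_b & .data$dose2 == dose_b) |
           (.data$agent1 == agent_b & .data$dose1 == dose_b &
              .data$agent2 == agent_a & .data$dose2 == dose_a))
    )
    if (nrow(m) == 0) {
      abort(sprintf("no combination wells for %s %g + %s %g.",
                    agent_a, dose_a, agent_b, dose_b))
    }
    effects <- m$effect
  }
  if (length(effects) < 2) abort("combination needs >= 2 replicate effects.")
  structure(list(agent_a = agent_a, dose_a = dose_a,
                 agent_b = agent_b, dose_b = dose_b,
                 effects = effects, mean = mean(effects),
                 se = sd(effects) / sqrt(length(effects)),
                 n = length(effects)),
            class = "combo_obs")
}

#' @export
print.combo_obs <- function(x, ...) {
  cat(sprintf("<combo_obs> %s %g uM + %s %g uM: effect %.1f%% +/- %.1f (SE), n = %d\n",
              x$agent_a, x$dose_a, x$agent_b, x$dose_b, x$mean, x$se, x$n))
  invisible(x)
}
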