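#' Simulate a viability plate assay
#'
#' Draws one plate of well records from an [assay_truth()]: `n_control`
#' untreated control wells, `n` replicate wells at every single-agent dose,
#' and `n` replicate wells at the combination (if any). Treated-well
#' absorbance follows the generative model
#' `A = control_mean * (100 - true_effect - eps) / 100` with
#' `eps ~ Normal(0, sigma)`; control wells are
#' `Normal(control_mean, control_mean * control_cv)`. Absorbances are floored
#' at a tiny positive value since an optical density cannot be negative.
#'
#' The same seed and truth always produce a bit-identical plate. Output uses
#' the plate CSV schema consumed by [read_plate_csv()] and
#' [normalize_viability()], and carries no ground-truth columns.
#'
#' @param truth An [assay_truth()] object.
#' @param seed Integer seed; defaults to the seed stored in `truth`. `NULL`
#'   uses the current RNG stream.
#' @param plate_id Plate label for all wells.
#' @return A tibble of well records with columns `plate_id`, `condition_id`,
#'   `agent1`, `dose1`, `agent2`, `dose2`, `dose_unit`, `absorbance`,
#'   `replicate`, `is_control`.
#' @examples
#' plate <- simulate_plate(assay_truth(seed = 1))
#' head(plate)
#' @export
simulate_plate <- function(truth, seed = truth$seed, plate_id = "plate1") {
  if (!inherits(truth, "assay_truth")) abort("`truth` must be an assay_truth object.")

  conditions <- list()
  conditions[[length(conditions) + 1L]] <- tibble(
    condition_id = "control", agent1 = NA_character_, dose1 = 0,
    agent2 = NA_character_, dose2 = 0, effect = 0,
    k = truth$n_control, control = TRUE
  )
  for (nm in names(truth$agents)) {
    ag <- truth$agents[[nm]]
    conditions[[length(conditions) + 1L]] <- tibble(
      condition_id = sprintf("%s_%g", nm, ag$doses),
      agent1 = nm, dose1 = ag$doses,
      agent2 = NA_character_, dose2 = 0,
      effect = ag$effect(ag$doses), k = truth$n, control = FALSE
    )
  }
  if (!is.null(truth$combo)) {
    cb <- truth$combo
    conditions[[length(conditions) + 1L]] <- tibble(
      condition_id = sprintf("%s_%g+%s_%g", cb$agent_a, cb$dose_a,
                             cb$agent_b, cb$dose_b),
      agent1 = cb$agent_a, dose1 = cb$dose_a,
      agent2 = cb$agent_b, dose2 = cb$dose_b,
      effect = cb$effect, k = truth$n, control = FALSE
    )
  }
  cond <- dplyr::bind_rows(conditions)

  wells <- with_seed_maybe(seed, {
    rows <- tidyr::uncount(cond, weights = .data$k, .id = "replicate")
    n_ctrl <- sum(rows$control)
    ctrl_abs <- rnorm(n_ctrl, truth$control_mean,
                      truth$control_mean * truth$control_cv)
    eps <- rnorm(nrow(rows) - n_ctrl, 0, truth$sigma)
    a <- numeric(nrow(rows))
    a[rows$control] <- ctrl_abs
    a[!rows$control] <- truth$control_mean *
      (100 - rows$effect[!rows$control] - eps) / 100
    rows$absorbance <- pmax(a, 1e-9 * truth$control_mean)
    rows
  })

  tibble(plate_id = plate_id,
         condition_id = wells$condition_id,
         agent1 = wells$agent1, dose1 = wells$dose1,
         agent2 = wells$agent2, dose2 = wells$dose2,
         dose_unit = "uM",
         absorbance = wells$absorbance,
         replicate = as.integer(wells$replicate),
         is_control = wells$control)
}

#' Simulate xenograft tumor growth measurements
#'
#' Draws caliper measurements from a [growth_truth()]: per animal, the true
#' volume follows `V(t) = V0 * exp(rate * t)` with a log-normal baseline
#' `V0` (median `baseline`, CV `baseline_cv`); each volume is encoded as a
#' caliper pair (`L = aspect * W`, `V = L * W^2 / 2`) and both dimensions
#' receive independent multiplicative log-normal noise with CV `noise_cv`.
#' Lengths and widths are therefore strictly positive by construction, and
#' the same seed always reproduces the dataset bit-for-bit.
#'
#' @param truth A [growth_truth()] object.
#' @param seed Integer seed; defaults to the seed stored in `truth`.
#' @return A tibble of measurements with columns `animal_id`, `group`, `day`,
#'   `length_mm`, `width_mm`, matching the schema of [read_tumor_csv()].
#' @examples
#' head(simulate_growth(growth_truth(seed = 1)))
#' @export
simulate_growth <- function(truth, seed = truth$seed) {
  if (!inherits(truth, "growth_truth")) abort("`truth` must be a growth_truth object.")
  sdlog_b <- sqrt(log(1 + truth$baseline_cv^2))
  sdlog_m <- sqrt(log(1 + truth$noise_cv^2))

  with_seed_maybe(seed, {
    groups <- names(truth$rates)
    out <- vector("list", sum(truth$n_per_group))
    animal <- 0L
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      for (j in seq_len(truth$n_per_group[gi])) {
        animal <- animal + 1L
        v0 <- truth$baseline * exp(rnorm(1, 0, sdlog_b))
        v <- v0 * exp(truth$rates[gi] * truth$days)
        w <- (2 * v / truth$aspect)^(1 / 3)
        l <- truth$aspect * w
        l <- l * exp(rnorm(length(l), 0, sdlog_m))
        w <- w * exp(rnorm(length(w), 0, sdlog_m))
        out[[animal]] <- tibble(
          animal_id = sprintf("m%02d", animal), group = g,
          day = as.integer(truth$days),
          length_mm = pmax(l, w), width_mm = pmin(l, w)
        )
      }
    }
    dplyr::bind_rows(out)
  })
}
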