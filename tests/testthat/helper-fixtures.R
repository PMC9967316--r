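# programmatic fixtures shared across tests

# replicate-level effect curve around a linear truth effect = slope * dose
make_linear_curve <- function(slope, doses, n = 3, sigma = 0, seed = NULL,
                              agent = "agent") {
  gen <- function() {
    df <- data.frame(dose = rep(doses, each = n))
    df$effect <- slope * df$dose + rnorm(nrow(df), 0, sigma)
    df
  }
  df <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  effect_curve(df, agent)
}

# random strictly-increasing 5-point curve on (0, 100]
random_monotone_curve <- function(max_dose = 100) {
  doses <- sort(runif(5, 1, max_dose))
  means <- cumsum(runif(5, 1, 20))
  df <- data.frame(dose = rep(doses, each = 2),
                   effect = rep(means, each = 2))
  suppressWarnings(effect_curve(df))
}

# a tumor_series tibble built directly from group -> volumes at one day
series_from_volumes <- function(vols, day = 42) {
  purrr::imap_dfr(vols, function(v, g) {
    tibble::tibble(animal_id = sprintf("%s_%d", g, seq_along(v)),
                   group = g, day = day, volume = v)
  })
}
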