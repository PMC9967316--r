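# plate and xenograft simulators: generative model, validation, determinism

test_that("same seed and truth give bit-identical simulated datasets", {
  truth <- assay_truth(seed = 11)
  expect_identical(simulate_plate(truth), simulate_plate(truth))
  gt <- growth_truth(seed = 11)
  expect_identical(simulate_growth(gt), simulate_growth(gt))
  # different seeds differ
  expect_false(identical(simulate_plate(truth, seed = 12), simulate_plate(truth)))
})

test_that("zero-noise wells follow the absorbance model exactly", {
  truth <- assay_truth(
    agents = list(x = list(effect = function(d) pmin(100, d),
                           doses = c(25, 50, 75))),
    combo = NULL, n = 2, sigma = 0, control_mean = 1, control_cv = 0,
    seed = 1
  )
  plate <- simulate_plate(truth)
  at50 <- plate$absorbance[!is.na(plate$agent1) & plate$dose1 == 50]
  expect_equal(at50, rep(0.5, 2))          # A = 1 * (100 - 50) / 100
  ctrl <- plate$absorbance[plate$is_control]
  expect_equal(ctrl, rep(1, truth$n_control))  # f(0) = 0, no noise
})

test_that("simulated effects match the stated noise model (Monte Carlo)", {
  truth <- assay_truth(
    agents = list(x = list(effect = function(d) pmin(100, 1.5 * d),
                           doses = c(10, 25, 40))),
    combo = NULL, n = 200, sigma = 5, control_cv = 0, seed = 42
  )
  viab <- normalize_viability(simulate_plate(truth))
  eff40 <- viab$effect[!is.na(viab$agent1) & viab$dose1 == 40]
  expect_length(eff40, 200)
  expect_lt(abs(mean(eff40) - 60), 3 * 5 / sqrt(200))
})

test_that("assay ground truth is validated at construction", {
  expect_error(assay_truth(agents = list(x = list(
    effect = function(d) -d, doses = c(1, 2, 3)))), "non-decreasing")
  expect_error(assay_truth(agents = list(x = list(
    effect = function(d) d + 5, doses = c(1, 2, 3)))), "f\\(0\\)")
  expect_error(assay_truth(agents = list(x = list(
    effect = function(d) d, doses = c(-1, 2, 3)))), "negative dose")
  expect_error(assay_truth(n = 1), "`n`")
  expect_error(assay_truth(sigma = -1), "`sigma`")
})

test_that("noise-free growth follows the exponential closed form", {
  gt0 <- growth_truth(baseline = 100, rates = c(g = 0), n_per_group = 3,
                      days = c(0, 7, 14), noise_cv = 0, baseline_cv = 0,
                      seed = 1)
  s <- tumor_series(simulate_growth(gt0))
  expect_equal(s$volume, rep(100, 9), tolerance = 1e-12)

  gt2 <- growth_truth(baseline = 100, rates = c(g = log(2) / 7),
                      n_per_group = 2, days = c(0, 7), noise_cv = 0,
                      baseline_cv = 0, seed = 1)
  s2 <- tumor_series(simulate_growth(gt2))
  expect_equal(s2$volume[s2$day == 7], rep(200, 2), tolerance = 1e-10)
})

test_that("noisy growth means match the closed form within Monte Carlo error", {
  gt <- growth_truth(baseline = 100, rates = c(g = 0.1), n_per_group = 100,
                     days = c(0, 7), noise_cv = 0.05, baseline_cv = 0,
                     seed = 5)
  s <- tumor_series(simulate_growth(gt))
  v7 <- s$volume[s$day == 7]
  # measured V = true V * exp(a + 2b), a,b ~ N(0, sdlog^2) on L and W
  sdlog <- sqrt(log(1 + 0.05^2))
  expected <- 100 * exp(0.7) * exp(5 * sdlog^2 / 2)
  expect_lt(abs(mean(v7) - expected), 3 * sd(v7) / sqrt(100))
  expect_true(all(s$volume > 0))
})

test_that("growth truth rejects degenerate designs", {
  expect_error(growth_truth(rates = c(g = Inf)), "finite")
  expect_error(growth_truth(baseline = 0), "baseline")
  expect_error(growth_truth(n_per_group = 0), ">= 1 animal")
})

test_that("noise-free pipeline recovers ED of a linear truth exactly", {
  m <- 1.2
  truth <- assay_truth(
    agents = list(x = list(effect = function(d) pmin(100, m * d),
                           doses = c(10, 25, 40, 60, 80))),
    combo = NULL, n = 2, sigma = 0, control_cv = 0, seed = 3
  )
  curve <- build_effect_curve(normalize_viability(simulate_plate(truth)), "x")
  for (e in c(20, 50, 75)) {
    expect_equal(interpolate_ed(curve, e)$estimate, e / m, tolerance = 1e-6)
  }
})
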