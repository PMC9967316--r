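# linear screen, effective-dose interpolation, bootstrap CIs

test_that("linear screen recovers exact and degenerate fits", {
  curve <- make_linear_curve(2, c(10, 20, 30, 40), n = 2)
  fit <- fit_linear(curve)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$p_value, 0)

  flat <- suppressWarnings(effect_curve(data.frame(dose = c(1, 2, 3),
                                                   effect = c(7, 7, 7))))
  ffit <- fit_linear(flat)
  expect_equal(ffit$slope, 0)
  expect_equal(ffit$statistic, 0)
  expect_equal(ffit$p_value, 1)

  same <- suppressWarnings(effect_curve(data.frame(dose = c(5, 5, 5) + 0,
                                                   effect = c(1, 2, 3))))
  expect_error(fit_linear(same), "dose points|identical")
})

test_that("linear screen matches the closed-form OLS oracle", {
  withr::with_seed(10, {
    for (i in 1:20) {
      x <- sort(runif(5, 0, 100))
      y <- 0.8 * x + rnorm(5, 0, 6)
      curve <- suppressWarnings(effect_curve(data.frame(dose = x, effect = y)))
      fit <- fit_linear(curve)
      # hand-rolled OLS + F
      sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
      slope <- sxy / sxx
      yhat <- mean(y) + slope * (x - mean(x))
      ssr <- sum((yhat - mean(y))^2); sse <- sum((y - yhat)^2)
      f <- ssr / (sse / 3)
      expect_equal(fit$slope, slope, tolerance = 1e-10)
      expect_equal(fit$statistic, f, tolerance = 1e-10)
      expect_equal(fit$p_value, pf(f, 1, 3, lower.tail = FALSE), tolerance = 1e-10)
    }
  })
})

test_that("interpolation reproduces nodes exactly and refuses extrapolation", {
  curve <- suppressWarnings(effect_curve(
    data.frame(dose = c(0, 50, 100), effect = c(0, 50, 100))))
  expect_equal(interpolate_ed(curve, 50)$estimate, 50)

  withr::with_seed(2, {
    for (i in 1:25) {
      cv <- random_monotone_curve()
      for (j in seq_len(nrow(cv))) {
        expect_identical(interpolate_ed(cv, cv$mean_effect[j])$estimate,
                         cv$dose[j])
      }
      expect_error(interpolate_ed(cv, max(cv$mean_effect) + 1), "unreachable")
    }
  })
  expect_error(interpolate_ed(suppressWarnings(effect_curve(
    data.frame(dose = c(1, 2), effect = c(1, 2)))), 1), ">= 3 dose points")
})

test_that("ED interpolation matches a dense-grid + bisection root oracle", {
  oracle_ed <- function(curve, e) {
    d <- c(0, curve$dose); m <- c(0, curve$mean_effect)
    sf <- splinefun(d, m, method = "monoH.FC")
    grid <- seq(0, max(d), length.out = 20001)
    v <- sf(grid) - e
    hit <- which(v[-length(v)] * v[-1] <= 0)[1]
    lo <- grid[hit]; hi <- grid[hit + 1]
    for (k in 1:60) {  # plain bisection, independent of uniroot
      mid <- (lo + hi) / 2
      if ((sf(lo) - e) * (sf(mid) - e) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  withr::with_seed(3, {
    for (i in 1:50) {
      cv <- random_monotone_curve()
      e <- runif(1, 1, max(cv$mean_effect) * 0.99)
      expect_equal(interpolate_ed(cv, e)$estimate, oracle_ed(cv, e),
                   tolerance = 1e-6 * max(cv$dose))
    }
  })
})

test_that("non-monotone curves return the first (smallest) crossing", {
  curve <- suppressWarnings(effect_curve(
    data.frame(dose = c(10, 20, 30, 40), effect = c(30, 10, 25, 60))))
  ed <- interpolate_ed(curve, 20)$estimate
  # brute-force scan: first grid dose where the interpolant reaches 20
  sf <- splinefun(c(0, curve$dose), c(0, curve$mean_effect), method = "monoH.FC")
  grid <- seq(0, 40, length.out = 400001)
  first <- grid[which(sf(grid) >= 20)[1]]
  expect_lt(abs(ed - first), 1e-3)
  expect_lt(ed, 10)  # crossing on the rising flank before the first node
})

test_that("interpolant is monotone in the effect level and never overshoots", {
  withr::with_seed(4, {
    for (i in 1:20) {
      cv <- random_monotone_curve()
      es <- sort(runif(4, 1, max(cv$mean_effect)))
      eds <- vapply(es, function(e) interpolate_ed(cv, e)$estimate, 1)
      expect_true(all(diff(eds) >= -1e-9))

      d <- c(0, cv$dose); m <- c(0, cv$mean_effect)
      sf <- splinefun(d, m, method = "monoH.FC")
      for (seg in seq_len(length(d) - 1)) {
        x <- seq(d[seg], d[seg + 1], length.out = 50)
        expect_true(all(sf(x) >= m[seg] - 1e-9 & sf(x) <= m[seg + 1] + 1e-9))
      }
    }
  })
})

test_that("bootstrap CIs are deterministic given a seed and collapse at zero noise", {
  cv <- make_linear_curve(1, c(10, 30, 50, 70), n = 4, sigma = 6, seed = 9)
  e1 <- bootstrap_ed(cv, 40, B = 500, seed = 21)
  e2 <- bootstrap_ed(cv, 40, B = 500, seed = 21)
  expect_identical(tidy(e1), tidy(e2))
  expect_false(identical(tidy(bootstrap_ed(cv, 40, B = 500, seed = 22)), tidy(e1)))

  noiseless <- make_linear_curve(1, c(10, 30, 50, 70), n = 3, sigma = 0)
  ci <- bootstrap_ed(noiseless, 40, B = 500, seed = 1)
  expect_equal(ci$conf_low, 40)
  expect_equal(ci$conf_high, 40)
  expect_equal(ci$estimate, 40)
})

test_that("resamples that miss the effect level are dropped and counted", {
  # right-skewed top dose: ~30% of resampled curves never reach E = 30
  df <- data.frame(dose = rep(c(10, 20, 30), each = 3),
                   effect = c(2, 3, 4, 8, 10, 12, 0, 0, 90))
  cv <- effect_curve(df)
  ed <- bootstrap_ed(cv, 30, B = 1000, seed = 5)
  expect_gt(ed$n_unreachable, 150)   # P(no 90 in a resample) = (2/3)^3
  expect_lt(ed$n_unreachable, 450)
  expect_true(ed$conf_low <= ed$conf_high)
  expect_equal(ed$B, 1000L)
})
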