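# potency ratios, G-test, interaction index, envelopes, classification,
# effect-level escalation

# exact ED estimates via node-exact interpolation
exact_ed <- function(ed50, effect = 50, agent = "a") {
  slope <- 50 / ed50
  doses <- c(ed50 * 0.4, ed50, ed50 * 1.8)
  df <- data.frame(dose = rep(doses, each = 2),
                   effect = rep(slope * doses, each = 2))
  interpolate_ed(effect_curve(df, agent), effect)
}

test_that("potency ratio matches the worked 51/44 example and its symmetries", {
  ed_nx <- exact_ed(51, agent = "naloxone")
  ed_cis <- exact_ed(44, agent = "cisplatin")
  r <- potency_ratio(ed_nx, ed_cis)
  expect_equal(round(r$ratio, 2), 1.16)
  expect_equal(potency_ratio(ed_cis, ed_nx)$ratio, 1 / r$ratio)
  expect_equal(potency_ratio(ed_nx, ed_nx)$ratio, 1)
  expect_error(potency_ratio(ed_nx, exact_ed(44, effect = 30)), "effect levels differ")
})

test_that("maximum common effect is the min of the curve maxima", {
  a <- make_linear_curve(1, c(10, 50, 92), n = 2)   # max mean effect 92
  b <- make_linear_curve(1, c(10, 50, 100), n = 2)  # max mean effect 100
  expect_equal(max_common_effect(a, b), 92)
  expect_equal(max_common_effect(b, b), 100)
  withr::with_seed(8, {
    for (i in 1:10) {
      x <- random_monotone_curve(); y <- random_monotone_curve()
      expect_equal(max_common_effect(x, y),
                   min(max(x$mean_effect), max(y$mean_effect)))
    }
  })
})

test_that("G statistic matches the hand formula and its edge cases", {
  # identical row proportions -> no evidence of difference
  g0 <- g_test(matrix(c(20, 40, 10, 20), nrow = 2))
  expect_equal(g0$statistic, 0, tolerance = 1e-12)
  expect_equal(g0$p_value, 1)

  g1 <- g_test(matrix(c(30, 10, 10, 30), nrow = 2))
  expect_equal(round(g1$statistic, 2), 20.93)

  withr::with_seed(12, {
    for (i in 1:20) {
      tab <- matrix(rpois(4, 20) + 1, nrow = 2)
      got <- g_test(tab)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      g_hand <- 2 * sum(tab * log(tab / expected))
      expect_equal(got$statistic, g_hand, tolerance = 1e-10)
      expect_equal(got$p_value, pchisq(g_hand, 1, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  })

  expect_message(gz <- g_test(matrix(c(5, 3, 0, 0), nrow = 2)), "continuity")
  expect_true(is.finite(gz$statistic))
})

test_that("ratio draws on the same side of one give a non-significant constancy test", {
  mk_ratio <- function(draws, effect) {
    structure(list(agent_a = "a", agent_b = "b", effect = effect,
                   ratio = mean(draws), conf_low = NA, conf_high = NA,
                   conf_level = NA, draws = draws),
              class = "potency_ratio")
  }
  withr::with_seed(13, {
    r50 <- mk_ratio(exp(rnorm(500, log(1.16), 0.03)), 50)   # all > 1
    rmx <- mk_ratio(exp(rnorm(500, log(1.07), 0.015)), 95)
  })
  ct <- suppressMessages(constancy_gtest(r50, rmx))
  expect_gt(ct$p_value, 0.05)
  expect_true(ct$linear_isobole)

  # opposite sides -> strong evidence against a constant ratio
  r_lo <- mk_ratio(exp(rnorm(500, log(0.7), 0.05)), 95)
  ct2 <- suppressMessages(constancy_gtest(r50, r_lo))
  expect_lt(ct2$p_value, 0.001)
  expect_false(ct2$linear_isobole)
})

test_that("interaction index embodies the linear isobole", {
  expect_equal(interaction_index(0, 44, 51, 44), 1)
  expect_equal(interaction_index(51 / 2, 44 / 2, 51, 44), 1)
  expect_equal(round(interaction_index(10, 20, 51, 44), 3), 0.651)
  expect_equal(interaction_index(10, 20, 51, 44), 10 / 51 + 20 / 44,
               tolerance = 1e-15)
  # every point on the additivity line has gamma exactly 1
  withr::with_seed(14, {
    for (i in 1:25) {
      ed_a <- runif(1, 5, 100); ed_b <- runif(1, 5, 100); t <- runif(1)
      expect_equal(interaction_index(t * ed_a, (1 - t) * ed_b, ed_a, ed_b), 1,
                   tolerance = 1e-12)
    }
  })
  expect_error(interaction_index(10, 20, 0, 44), "ed_a")
})

with_draws <- function(ed, draws) { ed$draws <- draws; ed }

test_that("envelope reduces to the line at zero variance and to the marginal CI at a = 0", {
  ed_a <- with_draws(exact_ed(51), rep(51, 400))
  ed_b <- with_draws(exact_ed(44, agent = "b"), rep(44, 400))
  env <- isobole_envelope(ed_a, ed_b)
  expect_equal(env$grid$lower, env$grid$line, tolerance = 1e-12)
  expect_equal(env$grid$upper, env$grid$line, tolerance = 1e-12)

  withr::with_seed(15, {
    db <- 44 * exp(rnorm(400, 0, 0.1))
    ed_b2 <- with_draws(exact_ed(44, agent = "b"), db)
    env2 <- isobole_envelope(ed_a, ed_b2)
    q <- unname(quantile(db, c(0.025, 0.975), type = 7))
    expect_equal(env2$grid$lower[1], q[1])
    expect_equal(env2$grid$upper[1], q[2])
  })
})

test_that("envelope bounds are ordered around the central line", {
  withr::with_seed(16, {
    for (i in 1:10) {
      ed_a <- with_draws(exact_ed(51), 51 * exp(rnorm(300, 0, 0.15)))
      ed_b <- with_draws(exact_ed(44, agent = "b"), 44 * exp(rnorm(300, 0, 0.15)))
      env <- isobole_envelope(ed_a, ed_b)
      expect_true(all(env$grid$lower <= env$grid$upper + 1e-12))
      inner <- env$grid$dose_a <= 51  # within the central line's support
      expect_true(all(env$grid$lower[inner] <= env$grid$line[inner] + 1e-9))
      expect_true(all(env$grid$upper[inner] >= env$grid$line[inner] - 1e-9))
    }
  })
})

test_that("combinations are classified by envelope position and interaction index", {
  withr::with_seed(17, {
    ed_a <- with_draws(exact_ed(51), 51 * exp(rnorm(500, 0, 0.08)))
    ed_b <- with_draws(exact_ed(44, agent = "b"), 44 * exp(rnorm(500, 0, 0.08)))
  })
  env <- isobole_envelope(ed_a, ed_b)

  on_line <- classify_combination(env, 51 / 2, 44 / 2)
  expect_identical(on_line$verdict, "additive-consistent")
  expect_equal(on_line$gamma, 1)

  deep <- classify_combination(env, 5, 2)        # far below the envelope
  expect_identical(deep$verdict, "synergistic")
  expect_lt(deep$gamma, 1)
  expect_lt(2, deep$line)

  high <- classify_combination(env, 40, 44)      # far above
  expect_identical(high$verdict, "antagonistic-consistent")

  barely <- classify_combination(env, 51 / 2, 44 / 2 * 0.97)  # inside band, gamma < 1
  expect_identical(barely$verdict, "inconclusive")
  expect_lt(barely$gamma, 1)
})

test_that("effect level escalates only on significant supra-50% combinations", {
  all50 <- escalate_effect_level(c(50, 50, 50))
  expect_equal(all50$statistic, 0)
  expect_equal(all50$level, 50)

  s <- 7.8 * sqrt(3)  # SE 7.8 at n = 3
  obs <- 84.6 + s * c(-1, 0, 1)
  dec <- escalate_effect_level(obs)
  expect_equal(mean(obs), 84.6)
  expect_lt(dec$p_value, 0.05)
  expect_equal(dec$level, 84)

  weak <- escalate_effect_level(c(40, 60, 80))  # mean 60, wide spread
  expect_gt(weak$p_value, 0.05)
  expect_equal(weak$level, 50)

  below <- escalate_effect_level(c(20, 21, 22))  # significant but below 50
  expect_lt(below$p_value, 0.05)
  expect_equal(below$level, 50)

  expect_error(escalate_effect_level(c(84)), ">= 2 replicate")
})

test_that("swapping the agents inverts the ratio and preserves gamma and verdict", {
  viab <- normalize_viability(simulate_plate(assay_truth(seed = 31)))
  a <- build_effect_curve(viab, "naloxone")
  b <- build_effect_curve(viab, "cisplatin")
  combo_ab <- combination_observation(viab, "naloxone", "cisplatin", 10, 20)
  combo_ba <- combination_observation(viab, "cisplatin", "naloxone", 20, 10)

  f_ab <- assess_synergy(a, b, combo_ab, B = 400, seed = 31)
  f_ba <- assess_synergy(b, a, combo_ba, B = 400, seed = 31)

  expect_equal(f_ba$r50$ratio, 1 / f_ab$r50$ratio, tolerance = 1e-12)
  expect_equal(f_ba$levels$ed_a, f_ab$levels$ed_b)
  expect_equal(f_ba$levels$ed_b, f_ab$levels$ed_a)
  expect_equal(f_ba$levels$gamma, f_ab$levels$gamma, tolerance = 1e-12)
  expect_identical(f_ba$verdict, f_ab$verdict)
  expect_equal(f_ba$analysis_level, f_ab$analysis_level)
})
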