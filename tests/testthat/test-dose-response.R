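test_that("shmt_rate matches closed forms and is monotone", {
  expect_equal(shmt_rate(0, 50, 3), 1)
  expect_equal(shmt_rate(0, 200, 1), 1)
  expect_equal(shmt_rate(60, 60, 1), exp(-1))
  expect_equal(shmt_rate(100, 50, 3), 1 - (1 - exp(-2))^3)

  for (pars in list(c(50, 1), c(60, 5), c(186, 6.33))) {
    r <- shmt_rate(seq(0, 500, 10), pars[1], pars[2])
    expect_true(all(diff(r) <= 0))
    expect_true(all(r >= 0 & r <= 1))
  }

  expect_error(shmt_rate(10, -5, 2), "d0")
  expect_error(shmt_rate(10, 50, 0.5), "extrapolation")
  expect_error(shmt_rate(-1, 50, 2), "non-negative")
})

test_that("shoulder dose obeys its closed-form identities", {
  expect_equal(shoulder_dose(100, 1), 0)
  expect_equal(shoulder_dose(100, exp(1)), 100)
  expect_equal(shoulder_dose(62.3, 6.33), 62.3 * log(6.33))
  expect_equal(round(shoulder_dose(62.3, 6.33)), 115)
  # strictly increasing in m
  ms <- seq(1, 20, 0.5)
  expect_true(all(diff(shoulder_dose(60, ms)) > 0))
  expect_error(shoulder_dose(100, 0.9), "extrapolation")
})

test_that("fit_shmt recovers noiseless parameters and finds the global minimum", {
  doses <- c(0, 40, 80, 120, 160, 200)
  obs <- tibble(dose = doses, rate = shmt_rate(doses, 60, 5))
  fit <- fit_shmt(obs)
  expect_true(fit$converged)
  expect_lt(abs(fit$d0 - 60) / 60, 0.01)
  expect_lt(abs(fit$m - 5) / 5, 0.05)
  expect_equal(fit$dq, fit$d0 * log(fit$m))

  oracle <- grid_search_sse(obs, c(30, 120), c(1, 10))
  expect_lte(fit$sse, oracle + 1e-10)

  # counts interface averages replicates before fitting
  obs2 <- tibble(dose = rep(doses, 2), n_total = 20,
                 n_effect = round(20 * shmt_rate(rep(doses, 2), 60, 5)))
  fit2 <- fit_shmt(obs2)
  expect_equal(fit2$n_obs, length(doses))

  expect_error(fit_shmt(obs[1:2, ]), "at least 3")
  expect_error(fit_shmt(tibble(dose = c(0, 50, 100), rate = c(1, 1, 1))),
               "degenerate")
})

test_that("noiseless recovery holds across shouldered and exponential curves", {
  doses <- seq(0, 400, length.out = 9)
  for (truth in list(c(60, 5), c(62.3, 6.33), c(120, 2), c(80, 1))) {
    obs <- tibble(dose = doses, rate = shmt_rate(doses, truth[1], truth[2]))
    fit <- fit_shmt(obs)
    expect_lt(abs(fit$d0 - truth[1]) / truth[1], 0.01)
    expect_lt(abs(fit$m - truth[2]) / truth[2], 0.05)
  }
})

test_that("dose_at_rate inverts the fitted curve to tolerance", {
  doses <- seq(0, 240, 40)
  fit <- fit_shmt(tibble(dose = doses, rate = shmt_rate(doses, 60, 5)))
  closed_form <- function(t) -fit$d0 * log(1 - (1 - t)^(1 / fit$m))

  # definition of D0: the dose where rate = 1 - (1 - e^-1)^m
  t_d0 <- 1 - (1 - exp(-1))^fit$m
  expect_equal(dose_at_rate(fit, t_d0), fit$d0, tolerance = 1e-3)

  d50 <- dose_at_rate(fit, 0.5)
  expect_equal(d50, closed_form(0.5), tolerance = 0.01)
  # 10x finer bisection oracle agrees
  expect_equal(dose_at_rate(fit, 0.5, tol = 0.001), closed_form(0.5),
               tolerance = 0.001)

  # single-hit curve: D50 = d0 * ln 2
  fit1 <- fit_shmt(tibble(dose = doses, rate = shmt_rate(doses, 60, 1)))
  expect_equal(dose_at_rate(fit1, 0.5), fit1$d0 * log(2), tolerance = 0.01)

  expect_error(dose_at_rate(fit, 1.2), "target_rate")
  expect_error(dose_at_rate(fit, 0), "target_rate")
})

test_that("rbe reproduces endpoint ratios and its algebraic identities", {
  expect_equal(round(rbe(343, 115)$rbe, 2), 2.98)
  # the printed endpoint doses are rounded to whole Gy, so the ratio of
  # printed doses can differ from the printed RBE in the last digit
  expect_equal(rbe(376, 142)$rbe, 2.64, tolerance = 0.005)
  expect_equal(rbe(200, 200)$rbe, 1)
  # rbe * test_dose = reference_dose to machine precision
  r <- rbe(263, 101)
  expect_equal(r$rbe * r$test_dose, r$reference_dose)
  # antitone in test dose
  expect_true(all(diff(rbe(300, c(50, 100, 150))$rbe) < 0))
  expect_error(rbe(0, 100), "positive")
  expect_error(rbe(100, -1), "positive")
})

test_that("fertility rate arithmetic and domain errors", {
  expect_equal(fertility_rate(100, 0, 0), 1)
  expect_equal(fertility_rate(100, 30, 20), 0.5)
  expect_equal(fertility_rate(10, 6, 4), 0)
  expect_error(fertility_rate(0, 0, 0), "positive")
  expect_error(fertility_rate(10, 8, 4), "exceed")
  expect_error(fertility_rate(10, -1, 0), "non-negative")
})

test_that("R-squared matches a two-pass oracle and flags zero variance", {
  doses <- seq(0, 200, 25)
  obs <- tibble(dose = doses, rate = shmt_rate(doses, 60, 5))
  fit <- fit_shmt(obs)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)

  set.seed(11)
  noisy <- tibble(dose = doses,
                  rate = pmin(1, pmax(0, obs$rate +
                                        rnorm(length(doses), 0, 0.03))))
  fitn <- fit_shmt(noisy)
  pred <- shmt_rate(doses, fitn$d0, fitn$m)
  oracle <- 1 - sum((noisy$rate - pred)^2) /
    sum((noisy$rate - mean(noisy$rate))^2)
  expect_equal(fitn$r_squared, oracle)

  flat <- tibble(dose = doses, rate = rep(0.5, length(doses)))
  expect_warning(r2 <- shmt_r_squared(fit, flat), "zero variance")
  expect_true(is.na(r2))
})

test_that("half-yield dose interpolates the first downward crossing", {
  expect_equal(yield_half_dose(tibble(dose = c(100, 140),
                                      relative_yield = c(0.6, 0.4))), 120)
  tbl <- tibble(dose = c(0, 40, 80, 120),
                relative_yield = c(1, 1.1, 0.9, 0.5))
  expect_equal(yield_half_dose(tbl), 120)
  expect_error(
    yield_half_dose(tibble(dose = c(0, 100), relative_yield = c(1, 0.8))),
    "never crosses")
})

test_that("binomially noised recovery keeps the shoulder dose estimable", {
  # study-like design: carbon dose grid, ~20 seeds per point
  set.seed(202)
  truth_dq <- 62.3 * log(6.33)
  rel_err <- replicate(200, {
    obs <- simulate_dose_response(d0 = 62.3, m = 6.33, n_units = 20)
    fit <- fit_shmt(obs, n_starts = 3)
    abs(fit$dq - truth_dq) / truth_dq
  })
  expect_lt(median(rel_err), 0.15)
})
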