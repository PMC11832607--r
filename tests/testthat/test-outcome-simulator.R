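test_that("event times follow the inversion formula", {
  # rates (1, 0.5, 0.5), zero linear predictors: denominator = 2, so
  # u1 = exp(-2) gives time exactly 1
  out <- simulate_events(matrix(0, 1, 3), c(1, 0.5, 0.5),
                         u1 = exp(-2), u2 = 0.4)
  expect_equal(out$time, 1)
  # u2 inversion against cumulative probabilities (0.5, 0.75, 1)
  expect_equal(simulate_events(matrix(0, 1, 3), c(1, 0.5, 0.5),
                               u1 = 0.5, u2 = 0.4)$event, 1L)
  expect_equal(simulate_events(matrix(0, 1, 3), c(1, 0.5, 0.5),
                               u1 = 0.5, u2 = 0.6)$event, 2L)
  expect_equal(simulate_events(matrix(0, 1, 3), c(1, 0.5, 0.5),
                               u1 = 0.5, u2 = 0.9)$event, 3L)
  expect_error(simulate_events(matrix(c(Inf, 0, 0), 1), c(1, 1, 1)),
               "non-finite")
})

test_that("event-type distribution follows the cause-specific rates", {
  n <- 1e5
  set.seed(4)
  lp <- matrix(0, n, 3)
  out <- simulate_events(lp, c(1, 1, 1))
  shares <- tabulate(out$event, 3) / n
  expect_true(all(abs(shares - 1/3) < 4 * sqrt((1/3) * (2/3) / n)))
  # vanishing third rate removes cause-3 events
  out0 <- simulate_events(lp[1:1e4, ], c(1, 1, 1e-12))
  expect_equal(sum(out0$event == 3L), 0L)
  # all-cause times are exponential with the summed rate
  rates <- c(1, 2, 2)
  out2 <- simulate_events(lp, rates)
  expect_lt(abs(mean(out2$time) - 1 / sum(rates)),
            4 / (sum(rates) * sqrt(n)))
})

test_that("censoring calibration hits the target and matches the
          closed-form quantile", {
  set.seed(5)
  T <- simulate_events(matrix(0, 2e4, 3), c(1, 1, 1))$time
  set.seed(6)
  u <- runif(2e4)
  cal <- calibrate_censoring(T, 0.25, u = u)
  expect_lte(abs(cal$realized - 0.25), 0.001)
  expect_equal(mean(cal$censor_time < T), cal$realized)
  # independent oracle: censored iff lambda_c > -log(u)/T, so the
  # calibrated rate must sit at the target quantile of that ratio
  r <- sort(-log(u) / T)
  k <- floor(0.25 * 2e4)
  expect_gt(cal$lambda_c, r[k - 25])
  expect_lt(cal$lambda_c, r[k + 26])
  # monotonicity under the same fixed uniforms
  fr <- function(l) mean(-log(u) / l < T)
  expect_true(all(diff(sapply(c(0.5, 1, 2, 4, 8) * cal$lambda_c, fr)) >= 0))
})

test_that("censoring calibration vanishes in the no-censoring limit", {
  set.seed(7)
  T <- rexp(5000, 3)
  cal <- calibrate_censoring(T, 0.002, tol = 0.002, u = runif(5000))
  expect_lt(cal$lambda_c, 0.05)
  expect_lte(cal$realized, 0.004)
})

test_that("super-population recovers the generating coefficients", {
  cfg <- scenario_config(rates = c(1, 1, 1), p_missing = 0.1,
                         n_super = 5e4, n_sample = 1000, n_reps = 1,
                         seed = 8)
  pop <- build_superpopulation(cfg)
  expect_lte(abs(pop$realized_censoring - 0.25), 0.001)
  expect_true(all(pop$data$time > 0))
  expect_true(all(pop$data$event %in% 0:3))
  B <- coef_matrix()
  # every fitted coefficient within 5 super-population standard errors
  for (k in 1:3) {
    f <- fit_cause_specific(pop$data, k)
    expect_lt(max(abs(f$beta - B[, k]) / f$se), 5)
  }
})

test_that("null covariate effects give null fitted coefficients", {
  betas <- default_coefficients()
  for (nm in names(betas)) betas[[nm]][] <- 0
  cfg <- scenario_config(rates = c(1, 2, 2), p_missing = 0.1,
                         n_super = 2e4, n_sample = 1000, n_reps = 1,
                         seed = 9)
  pop <- build_superpopulation(cfg, betas = betas)
  for (k in 1:3) {
    f <- fit_cause_specific(pop$data, k)
    expect_lt(max(abs(f$beta / f$se)), 4)
  }
  # uncensored event-type frequencies follow lambda_k / sum(lambda)
  ev <- pop$data$event[pop$data$event > 0]
  shares <- tabulate(ev, 3) / length(ev)
  expect_true(all(abs(shares - c(1, 2, 2) / 5) <
                    4 * sqrt(0.4 * 0.6 / length(ev))))
})
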