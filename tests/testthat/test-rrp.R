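test_that("EQ recovers pool and release probability exactly in pure depletion", {
  tr <- simulate_train(n0 = 1000, q = 10, p = 0.3, r = 0)
  est <- eq_estimate(tr)
  expect_equal(est$rrp_amplitude, 10, tolerance = 1e-9)
  expect_equal(est$pr, 0.3, tolerance = 1e-9)
  expect_equal(est$r_squared, 1, tolerance = 1e-9)
  expect_equal(est$slope, -0.3, tolerance = 1e-9)

  # inclusive-cumulative convention: same x-intercept, slope -p/(1-p)
  inc <- eq_estimate(tr, cumulative = "inclusive")
  expect_equal(inc$rrp_amplitude, 10, tolerance = 1e-9)
  expect_equal(inc$slope, -0.3 / 0.7, tolerance = 1e-9)

  # a non-depressing train has no EQ solution
  expect_error(eq_estimate(train_measurement(rep(2, 50), 100)), "EQ inapplicable")
  expect_error(eq_estimate(train_measurement(c(1, 0.5), 100)),
               class = "calyxq_validation_error")
})

test_that("SMN recovers pool, Pr and replenishment in the depletion model", {
  # r = 0: y-intercept = N0 q exactly, slope ~ 0 once the pool is exhausted
  # exact only up to the residual geometric term (1-p)^n ~ 2e-8 at n = 41
  tr <- simulate_train(n0 = 1000, q = 10, p = 0.35, r = 0)
  est <- smn_estimate(tr)
  expect_equal(est$rrp_amplitude, 10, tolerance = 1e-6)
  expect_lt(est$replenish_rate, 1e-6)
  expect_equal(est$pr, 0.35, tolerance = 1e-6)

  # with replenishment: asymptotic intercept N0 q - r q / p, slope r q
  n0 <- 800; q <- 40; p <- 0.45; r <- 40
  est <- smn_estimate(simulate_train(n0, q, p, r))
  expect_equal(est$rrp_amplitude, (n0 * q - r * q / p) / 1000, tolerance = 1e-9)
  expect_equal(est$replenish_rate, r * q / 1000, tolerance = 1e-9)

  expect_error(smn_estimate(train_measurement(rep(1, 12), 100)),
               class = "calyxq_validation_error")
})

test_that("estimators match independent closed-form oracles over a parameter grid", {
  set.seed(2024)
  n_grid <- 120
  ord_holds <- TRUE
  for (i in seq_len(n_grid)) {
    n0 <- runif(1, 200, 2000); q <- runif(1, 20, 80)
    p <- runif(1, 0.15, 0.6); r <- runif(1, 1e-3, 0.8 * p * n0)
    tr <- simulate_train(n0, q, p, r)
    eq <- eq_estimate(tr); smn <- smn_estimate(tr)
    o_eq <- oracle_eq(n0, q, p, r); o_smn <- oracle_smn(n0, q, p, r)
    expect_lt(abs(eq$rrp_amplitude - o_eq$x_intercept) / o_eq$x_intercept, 1e-9)
    expect_lt(abs(smn$rrp_amplitude - o_smn$y_intercept) / o_smn$y_intercept, 1e-9)
    truth <- n0 * q / 1000
    ord_holds <- ord_holds &&
      eq$rrp_amplitude >= truth - 1e-9 && truth >= smn$rrp_amplitude - 1e-9
  }
  # replenishment makes EQ a pre-existing-pool overestimate and SMN a
  # pool-decrement underestimate: EQ >= truth >= SMN
  expect_true(ord_holds)
})

test_that("estimators are time-shift invariant and amplitude covariant", {
  tr <- simulate_train(800, 40, 0.35, 56, mode = "binomial", seed = 5)
  shifted <- train_measurement(tr$amplitude_nA, freq = attr(tr, "freq_hz"),
                               stimulus_times = tr$time_ms + 250)
  scaled <- train_measurement(tr$amplitude_nA * 3, freq = attr(tr, "freq_hz"))
  for (fn in list(eq_estimate, smn_estimate)) {
    base <- fn(tr)
    expect_equal(fn(shifted)$rrp_amplitude, base$rrp_amplitude)
    expect_equal(fn(scaled)$rrp_amplitude, 3 * base$rrp_amplitude)
    expect_equal(fn(scaled)$pr, base$pr)  # Pr is dimensionless
  }
})

test_that("vesicle counts divide the pool by the quantal size", {
  expect_identical(vesicle_count(33.4, 39.9), 837L)
  expect_identical(vesicle_count(17.6, 33.4), 527L)
  expect_identical(vesicle_count(1, 1000), 1L)
  expect_error(vesicle_count(-1, 40), class = "calyxq_validation_error")
  expect_error(vesicle_count(10, 0), class = "calyxq_validation_error")
})

test_that("depression profile normalizes to the first response", {
  # the printed WT SMN parameters predict ~20% steady-state depression
  q <- 40
  tr <- simulate_train(n0 = 19.4 * 1000 / q, q = q, p = 0.35, r = 1.39 * 1000 / q)
  expect_equal(tr$amplitude_nA[1], 6.79, tolerance = 1e-9)
  dp <- depression_profile(tr)
  expect_equal(steady_state_ratio(dp), 1.39 / 6.79, tolerance = 1e-3)

  expect_equal(unique(depression_profile(train_measurement(rep(2, 50), 100))$normalized), 1)
  prof <- depression_profile(simulate_train(100, 10, 1, 0))
  expect_equal(prof$normalized, c(1, rep(0, 49)))
  expect_error(depression_profile(train_measurement(c(0, 1), 100)),
               class = "calyxq_validation_error")
})

test_that("rrp tidiers expose the estimate as tibbles", {
  est <- smn_estimate(simulate_train(800, 40, 0.35, 56), quantal_amp = 40)
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("rrp_amplitude", "pr", "replenish_rate") %in% td$term))
  gl <- glance(est)
  expect_equal(gl$method, "SMN")
  expect_equal(gl$vesicle_count, vesicle_count(est$rrp_amplitude, 40))
  expect_s3_class(autoplot(est), "ggplot")
  expect_s3_class(autoplot(eq_estimate(simulate_train(800, 40, 0.35, 0))), "ggplot")
})
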