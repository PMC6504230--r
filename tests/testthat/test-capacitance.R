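test_that("capacitance jumps are measured exactly up to the endocytosis window average", {
  # flat trace: no jump
  flat <- simulate_capacitance_sweeps("single_pulses", pulse_durations = 20,
                                      delta_cm_per_pulse = 0, post_ms = 300)
  expect_equal(measure_delta_cm(flat, 1)$delta_cm_fF, 0, tolerance = 1e-9)

  # slow endocytosis: window-average bias is the analytic integral of exp(-t/tau)
  ss <- simulate_capacitance_sweeps("single_pulses", pulse_durations = 20,
                                    delta_cm_per_pulse = 150, endo_tau = 20,
                                    post_ms = 300)
  m <- measure_delta_cm(ss, 1, artifact_skip = 50, post_window = 100)
  tau_ms <- 20000
  # discrete oracle: mean of the decayed jump over the sampled post window
  offs <- seq(50, 149.5, by = 0.5)
  expected <- 150 * mean(exp(-offs / tau_ms))
  expect_equal(m$delta_cm_fF, expected, tolerance = 1e-9)
  # and the continuous window-average integral agrees to ~1e-5
  cont <- 150 * tau_ms / 100 * (exp(-50 / tau_ms) - exp(-150 / tau_ms))
  expect_equal(expected, cont, tolerance = 1e-4)
  expect_equal(cont, 149.3, tolerance = 1e-3)
  expect_equal(m$resting_cm_pF, 20, tolerance = 1e-9)

  # fast endocytosis biases the measurement low, as the same integral predicts
  fast <- simulate_capacitance_sweeps("single_pulses", pulse_durations = 20,
                                      delta_cm_per_pulse = 150, endo_tau = 0.5,
                                      post_ms = 300)
  mf <- measure_delta_cm(fast, 1)
  expected_fast <- 150 * mean(exp(-offs / 500))
  expect_equal(mf$delta_cm_fF, expected_fast, tolerance = 1e-9)
  expect_lt(mf$delta_cm_fF, 130)
})

test_that("calcium charge integrates the pulse current and is offset invariant", {
  # rectangular -1 nA x 20 ms = 20 pC; density over 4 pF = 5 pC/pF
  si <- 0.5
  t <- seq(0, 400, by = si)
  im <- ifelse(t >= 100 & t < 120, -1000, 0)
  cols <- tibble::tibble(t_ms = t, `ch:cm:sweep1` = rep(4, length(t)),
                         `ch:im:sweep1` = im)
  ss <- sweep_set(cols, si, c(cm = "pF", im = "pA"),
                  protocol = list(pulse_times_ms = 100, pulse_durations_ms = 20))
  q <- integrate_ca_charge(ss, 1)
  expect_equal(q$q_ica_pC, 20, tolerance = 1e-9)
  expect_equal(q$q_ica_density_pC_pF, 5, tolerance = 1e-9)
  # holding-current offset changes nothing
  cols$`ch:im:sweep1` <- im - 250
  q2 <- integrate_ca_charge(sweep_set(cols, si, c(cm = "pF", im = "pA"),
                                      protocol = ss$protocol), 1)
  expect_equal(q2$q_ica_pC, 20, tolerance = 1e-9)
  # zero current, zero charge
  cols$`ch:im:sweep1` <- 0 * im
  expect_equal(integrate_ca_charge(sweep_set(cols, si, c(cm = "pF", im = "pA"),
                                             protocol = ss$protocol), 1)$q_ica_pC, 0)
})

test_that("the 20-pulse train analysis sums per-pulse jumps", {
  ss <- simulate_capacitance_sweeps("train_20x10ms_10Hz",
                                    delta_cm_per_pulse = rep(25, 20),
                                    endo_tau = 1e6, post_ms = 400)
  res <- analyze_cap_train(ss, fit_endo = FALSE)
  expect_equal(res$sigma_delta_cm_fF, 500, tolerance = 1e-5)
  expect_equal(res$normalized_timecourse$normalized[1], 1)
  expect_equal(res$normalized_timecourse$normalized[20], 20, tolerance = 1e-5)
  expect_equal(nrow(tidy(res)), 20)
  expect_equal(glance(res)$sigma_delta_cm_fF, 500, tolerance = 1e-5)

  # exactly 20 jumps at 100-ms spacing in the protocol
  expect_equal(length(ss$protocol$pulse_times_ms), 20)
  expect_equal(unique(diff(ss$protocol$pulse_times_ms)), 100)

  # depleting-pool jumps recover their own sum and stay below pool equivalent
  jumps <- 60 * 0.75^(0:19)
  ssd <- simulate_capacitance_sweeps("train_20x10ms_10Hz",
                                     delta_cm_per_pulse = jumps,
                                     endo_tau = 1e6, post_ms = 400)
  resd <- analyze_cap_train(ssd, fit_endo = FALSE)
  expect_equal(resd$per_pulse$delta_cm_fF, jumps, tolerance = 1e-4)
  expect_lte(resd$sigma_delta_cm_fF, 60 / 0.25)

  expect_error(analyze_cap_train(simulate_capacitance_sweeps("single_pulses")),
               "20 pulses")
  bad <- simulate_capacitance_sweeps("train_20x10ms_10Hz",
                                     delta_cm_per_pulse = c(0, rep(25, 19)),
                                     endo_tau = 1e6, post_ms = 400)
  expect_error(analyze_cap_train(bad, fit_endo = FALSE), "normalization undefined")
})

test_that("endocytosis tau is recovered from the post-train decay", {
  ss <- simulate_capacitance_sweeps("single_pulses", pulse_durations = 20,
                                    delta_cm_per_pulse = 300, endo_tau = 19.5,
                                    post_ms = 60000, sample_interval = 5)
  expect_equal(fit_endocytosis(ss, after_ms = 170), 19.5, tolerance = 1e-3)

  # noisy traces: mean over seeds within 3 SE of truth
  taus <- vapply(1:40, function(s) {
    ssn <- simulate_capacitance_sweeps("single_pulses", pulse_durations = 20,
                                       delta_cm_per_pulse = 300, endo_tau = 19.5,
                                       noise_sd_cm = 5, post_ms = 60000,
                                       sample_interval = 5, seed = s)
    fit_endocytosis(ssn, after_ms = 170)
  }, numeric(1))
  expect_lt(abs(mean(taus) - 19.5), 3 * sd(taus) / sqrt(length(taus)) + 0.1)

  # non-decaying trace is flagged
  flat <- simulate_capacitance_sweeps("single_pulses", pulse_durations = 20,
                                      delta_cm_per_pulse = 0, post_ms = 5000,
                                      sample_interval = 5)
  expect_warning(tau <- fit_endocytosis(flat, after_ms = 170), "does not decay")
  expect_true(is.na(tau))
})

test_that("I-V curves locate the peak inward current", {
  fam <- simulate_iv_family()
  curve <- iv_curve(fam)
  expect_equal(v_at_peak(curve), -10)
  expect_equal(min(curve$peak_pA), -626.7, tolerance = 1e-3)
  # zero current at the reversal potential
  rev <- iv_curve(simulate_iv_family(v_steps = c(-40, 45)))
  expect_equal(rev$peak_pA[rev$step_mv == 45], 0, tolerance = 1e-12)
  # zero conductance: all currents zero
  z <- iv_curve(simulate_iv_family(ca_gmax = 0))
  expect_true(all(abs(z$peak_pA) < 1e-12))
  # duplicate potentials rejected
  expect_error(iv_curve(simulate_iv_family(v_steps = c(-10, -10))),
               class = "calyxq_validation_error")
  expect_s3_class(autoplot(curve), "ggplot")
  # Boltzmann point check: g=4 nS, V=0, Vhalf=-20, k=5, Erev=45 -> -176.8 pA
  one <- iv_curve(simulate_iv_family(v_steps = 0, ca_gmax = 4, ca_vhalf = -20,
                                     ca_slope = 5, ca_erev = 45))
  expect_equal(one$peak_pA, 4 * (1 / (1 + exp(-4))) * (0 - 45), tolerance = 1e-9)
  expect_equal(one$peak_pA, -176.8, tolerance = 1e-3)
})
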