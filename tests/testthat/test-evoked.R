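make_epsc_sweep <- function(amp_nA = 5.9, baseline_pA = 0, tau = 1.0,
                            stim = 20, si = 0.02, dur = 60, noise = 0,
                            latency = 0.5, rise = 0.1) {
  t <- seq(0, dur, by = si)
  y <- baseline_pA - amp_nA * 1000 * biexp_event(t - stim - latency, rise, tau)
  if (noise > 0) y <- y + rnorm(length(t), 0, noise)
  as_current_sweep(y, si, protocol = list(stim_times_ms = stim))
}

test_that("p/4 leak subtraction cancels linear leak and keeps the signal", {
  si <- 0.02
  t <- seq(0, 50, by = si)
  leak <- 40 * sin(t / 3) + 100                 # any linear (scales with V) response
  signal <- -3000 * biexp_event(t - 20, 0.1, 1)
  cols <- tibble::tibble(t_ms = t,
                         `ch:im:sweep1` = leak + signal,
                         `ch:im:sweep2` = leak / 4,
                         `ch:im:sweep3` = leak / 4,
                         `ch:im:sweep4` = leak / 4,
                         `ch:im:sweep5` = leak / 4)
  ss <- sweep_set(cols, si, c(im = "pA"))
  corr <- p4_leak_subtract(ss)
  expect_equal(sweep_trace(corr, "im"), signal, tolerance = 1e-9)
  # purely ohmic trace corrects to zero
  cols0 <- cols
  cols0$`ch:im:sweep1` <- leak
  expect_equal(max(abs(sweep_trace(p4_leak_subtract(sweep_set(cols0, si, c(im = "pA"))), "im"))),
               0, tolerance = 1e-9)
  expect_error(p4_leak_subtract(sweep_set(cols[1:2], si, c(im = "pA"))),
               "missing p/4")
})

test_that("EPSC amplitude is the baseline-subtracted peak in nA", {
  expect_equal(measure_epsc(make_epsc_sweep(5.9), 20)$amplitude_nA, 5.9,
               tolerance = 1e-3)
  # baseline offsets subtract out
  m <- measure_epsc(make_epsc_sweep(3.2, baseline_pA = -100), 20)
  expect_equal(m$amplitude_nA, 3.2, tolerance = 1e-3)
  expect_equal(m$baseline_pA, -100, tolerance = 1e-6)
  # flat trace measures zero amplitude (and flags the degenerate peak)
  flat <- as_current_sweep(rep(-50, 3001), 0.02)
  expect_warning(m0 <- measure_epsc(flat, 20), "truncation")
  expect_equal(m0$amplitude_nA, 0)
  # gain covariance / offset invariance
  m2 <- measure_epsc(make_epsc_sweep(2 * 5.9, baseline_pA = 77), 20)
  expect_equal(m2$amplitude_nA, 2 * 5.9, tolerance = 1e-2)
})

test_that("evoked decay fits recover tau and ignore amplitude scale", {
  sw <- make_epsc_sweep(5.9, tau = 1.0)
  m <- fit_evoked_decay(sw, measure_epsc(sw, 20))
  expect_equal(m$decay_tau_ms, 1.0, tolerance = 0.02)
  sw2 <- make_epsc_sweep(11.8, tau = 1.0)
  m2 <- fit_evoked_decay(sw2, measure_epsc(sw2, 20))
  expect_equal(m2$decay_tau_ms, m$decay_tau_ms, tolerance = 0.01)
  # noisy traces: mean over seeds within 3 SE of the true constant
  taus <- vapply(1:60, function(s) {
    set.seed(s)
    swn <- make_epsc_sweep(5.9, tau = 1.0, noise = 0.02 * 5900)
    fit_evoked_decay(swn, measure_epsc(swn, 20))$decay_tau_ms
  }, numeric(1))
  expect_lt(abs(mean(taus) - 1.0), 3 * sd(taus) / sqrt(length(taus)) + 0.01)
})

test_that("paired-pulse ratio follows the depletion model", {
  expect_equal(paired_pulse_ratio(5, 4), 0.8)
  expect_equal(paired_pulse_ratio(5, 0), 0)
  expect_error(paired_pulse_ratio(0, 1), class = "calyxq_validation_error")

  # closed form from the pool recursion: A2/A1 = 1 - p + r/n0
  tr <- simulate_train(n0 = 1000, q = 10, p = 0.2, r = 0, n_stimuli = 2)
  expect_equal(paired_pulse_ratio(tr$amplitude_nA[1], tr$amplitude_nA[2]), 0.8,
               tolerance = 1e-12)
  set.seed(31)
  for (i in 1:15) {
    n0 <- runif(1, 200, 1500); p <- runif(1, 0.1, 0.7); r <- runif(1, 0, 0.8 * p * n0)
    tr <- simulate_train(n0, 40, p, r, n_stimuli = 2)
    expect_equal(paired_pulse_ratio(tr$amplitude_nA[1], tr$amplitude_nA[2]),
                 1 - p + r / n0, tolerance = 1e-10)
  }
})

test_that("two-pulse sweeps use a pre-pulse-2 baseline for the second amplitude", {
  si <- 0.02
  t <- seq(0, 60, by = si)
  a1 <- 5; a2 <- 4   # nA
  y <- -a1 * 1000 * biexp_event(t - 20.5, 0.1, 1.0) -
    a2 * 1000 * biexp_event(t - 30.5, 0.1, 1.0)
  ss <- as_current_sweep(y, si)
  res <- measure_ppr(ss, c(20, 30))
  expect_equal(res$a1_nA, a1, tolerance = 0.01)
  expect_equal(res$ppr, a2 / a1, tolerance = 0.01)
})

test_that("post-tetanic potentiation reports means, ratio and p-value", {
  pre <- c(5.5, 5.6, 5.7); post <- c(7.9, 8.0, 8.1)
  res <- ptp_analysis(pre, post)
  expect_equal(res$ratio, 8.0 / 5.6, tolerance = 1e-3)
  expect_lt(res$p_value, 0.05)
  expect_equal(glance(res)$post_mean, 8.0)
  expect_equal(tidy(res)$normalized, post / mean(pre))

  same <- ptp_analysis(pre, pre)
  expect_equal(same$ratio, 1)
  expect_equal(same$p_value, 1)

  # a tetanus that enlarges the pool by 40% potentiates amplitudes by 40%
  before <- simulate_train(1000, 10, 0.2, 0, n_stimuli = 1)$amplitude_nA
  after <- simulate_train(1400, 10, 0.2, 0, n_stimuli = 1)$amplitude_nA
  res2 <- ptp_analysis(rep(before, 3), rep(after, 3))
  expect_equal(res2$ratio, 1.4, tolerance = 1e-9)

  expect_error(ptp_analysis(c(1, 2), c(1, 2, 3)), class = "calyxq_validation_error")
})
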