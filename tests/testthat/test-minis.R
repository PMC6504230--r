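test_that("no events are reported in pure noise", {
  tr <- simulate_mini_trace(rate = 0, duration = 20, noise_sd = 2,
                            sample_interval = 0.2, seed = 101)
  ev <- detect_minis(tr, threshold_k = 5, min_amp = 10)
  expect_equal(nrow(ev), 0)
  expect_equal(mini_frequency(ev), 0)
})

test_that("detection recovers seeded events with high recall and precision", {
  tr <- simulate_mini_trace(rate = 4, duration = 30, amp_mean = 40,
                            noise_sd = 2, sample_interval = 0.05, seed = 42)
  truth <- tr$meta$truth$events
  ev <- detect_minis(tr)
  matched <- vapply(truth$onset_ms, function(t0)
    any(abs(ev$peak_ms - t0) < 3), logical(1))
  recall <- mean(matched)
  hit <- vapply(ev$peak_ms, function(tp)
    any(abs(truth$onset_ms - tp) < 3), logical(1))
  precision <- mean(hit)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  # amplitude bias < 5% of truth at this SNR (20:1)
  expect_lt(abs(mean(ev$amplitude_pA) - mean(truth$amplitude_pA)),
            0.05 * mean(truth$amplitude_pA))
})

test_that("events inside the refractory period merge to the larger peak", {
  si <- 0.05
  t <- seq(0, 4000, by = si)
  y <- 30 * biexp_event(t - 1000, 0.1, 0.6) +
    45 * biexp_event(t - 1001, 0.1, 0.6) +
    40 * biexp_event(t - 3000, 0.1, 0.6)
  set.seed(9); y <- y + rnorm(length(y), 0, 1)
  ev <- detect_minis(as_current_sweep(y, si), refractory = 5)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$peak_ms[1], 1001.2, tolerance = 0.3)
})

test_that("detection is translation invariant and gain covariant", {
  si <- 0.1
  base <- simulate_mini_trace(rate = 2, duration = 10, noise_sd = 2,
                              sample_interval = si, seed = 77)
  y <- sweep_trace(base, "im")
  ev0 <- detect_minis(base)
  # shift by 500 ms (circular pad with noise-free zeros replaced by noise tail)
  shift_n <- round(500 / si)
  y_sh <- c(y[(length(y) - shift_n + 1):length(y)], y[1:(length(y) - shift_n)])
  ev_sh <- detect_minis(as_current_sweep(y_sh, si))
  in_core <- ev0$peak_ms < (max(base$samples$t_ms) - 500)
  expect_equal(ev_sh$peak_ms[ev_sh$peak_ms >= 500], ev0$peak_ms[in_core] + 500,
               tolerance = si)
  # doubling the gain doubles amplitudes, leaves times alone
  ev2 <- detect_minis(as_current_sweep(2 * y, si), min_amp = 20)
  expect_equal(ev2$peak_ms, ev0$peak_ms, tolerance = si)
  expect_equal(ev2$amplitude_pA, 2 * ev0$amplitude_pA, tolerance = 0.05)
})

test_that("kinetics recover the true rise and decay of clean events", {
  si <- 0.02
  t <- seq(0, 3000, by = si)
  y <- 40 * biexp_event(t - 1000, 0.1, 0.6)
  set.seed(5)
  ev <- suppressWarnings(detect_minis(as_current_sweep(y + rnorm(length(y), 0, 1e-4), si), min_amp = 10))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$decay_tau_ms, 0.6, tolerance = 0.02)
  # shape invariance: scaling amplitude leaves kinetics unchanged
  y2 <- 80 * biexp_event(t - 1000, 0.1, 0.6)
  ev2 <- suppressWarnings(detect_minis(as_current_sweep(y2 + rnorm(length(y2), 0, 1e-4), si), min_amp = 10))
  expect_equal(ev2$rise_10_90_ms, ev$rise_10_90_ms, tolerance = 0.02)
  expect_equal(ev2$decay_tau_ms, ev$decay_tau_ms, tolerance = 0.02)
  # instant-rise event: 10-90% rise no slower than a sample step
  ystep <- 40 * ifelse(t < 1000, 0, exp(-(t - 1000) / 0.6))
  set.seed(6)
  evs <- detect_minis(as_current_sweep(ystep + rnorm(length(ystep), 0, 1e-4), si), min_amp = 10)
  expect_lte(evs$rise_10_90_ms, si + 1e-9)
})

test_that("frequency estimates recover the Poisson rate", {
  expect_equal(mini_frequency(tibble::tibble(x = 1:120)[rep(1, 120), ], 60), 2)
  freqs <- vapply(1:12, function(s) {
    tr <- simulate_mini_trace(rate = 2.4, duration = 60, amp_mean = 60,
                              noise_sd = 2, sample_interval = 0.2, seed = s)
    mini_frequency(detect_minis(tr))
  }, numeric(1))
  se <- sqrt(2.4 / 60 / length(freqs))    # Poisson SE of the mean rate
  expect_lt(abs(mean(freqs) - 2.4), 3 * se + 0.05)
})

test_that("event counts over seeds are Poisson-dispersed", {
  counts <- vapply(1:200, function(s)
    nrow(simulate_mini_trace(rate = 2, duration = 60, noise_sd = 0,
                             sample_interval = 1, seed = s)$meta$truth$events),
    numeric(1))
  se_mean <- sqrt(120 / 200)
  expect_lt(abs(mean(counts) - 120), 3 * se_mean)
  # index-of-dispersion test at alpha = 0.01
  stat <- (length(counts) - 1) * var(counts) / mean(counts)
  p <- 2 * min(pchisq(stat, df = length(counts) - 1),
               pchisq(stat, df = length(counts) - 1, lower.tail = FALSE))
  expect_gt(p, 0.01)
})

test_that("degenerate and resource-guard inputs error", {
  flat <- as_current_sweep(rep(0, 20000), 0.1)
  expect_error(detect_minis(flat), "degenerate")
  expect_error(simulate_mini_trace(rate = 1e6, duration = 100),
               class = "calyxq_validation_error")
  short <- as_current_sweep(rnorm(100), 0.1)
  expect_error(detect_minis(short), class = "calyxq_validation_error")
})

test_that("noiseless event peaks land at the analytic biexponential peak time", {
  tr <- simulate_mini_trace(rate = 0.5, duration = 4, noise_sd = 0,
                            amp_cv = 0, sample_interval = 0.01, seed = 12)
  truth <- tr$meta$truth$events
  expect_gt(nrow(truth), 0)
  y <- sweep_trace(tr, "im")
  t_star <- log(0.6 / 0.1) * 0.6 * 0.1 / (0.6 - 0.1)
  # single well-separated events: global max sits at onset + t*
  if (nrow(truth) == 1 || min(diff(truth$onset_ms)) > 10) {
    ipk <- which.max(y)
    expect_equal(sweep_time(tr)[ipk], truth$onset_ms[which.max(truth$amplitude_pA)] + t_star,
                 tolerance = 0.02)
    expect_equal(max(y), max(truth$amplitude_pA), tolerance = 0.01)
  }
})
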