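#' Simulate a miniature-EPSC trace
#'
#' Builds a continuous current trace as Gaussian noise plus superposed
#' biexponential events with Poisson onsets. Each event has the shape
#' `s(t) = A * (exp(-t/decay_tau) - exp(-t/rise_tau)) / s_peak`, normalised
#' so its peak equals `A` (the analytic peak time is
#' `t* = log(decay/rise) * decay * rise / (decay - rise)`). Event amplitudes
#' are truncated-normal at zero. Events are stored as positive deflections
#' (magnitude convention; the inward polarity of the physiological current
#' is recorded in metadata).
#'
#' @param rate Poisson event rate, Hz (>= 0).
#' @param duration Trace duration, s.
#' @param amp_mean Mean event amplitude, pA.
#' @param amp_cv Amplitude coefficient of variation (default 0.3).
#' @param rise_tau,decay_tau Event time constants, ms (`rise_tau < decay_tau`).
#' @param noise_sd Gaussian noise SD, pA.
#' @param sample_interval Sampling interval, ms (default 0.05 = 20 kHz).
#' @param seed Integer seed.
#' @return A [sweep_set()] with one `pA` channel `im`; the true event onsets
#'   and amplitudes are in `meta$truth$events`.
#' @export
simulate_mini_trace <- function(rate, duration, amp_mean = 40, amp_cv = 0.3,
                                rise_tau = 0.1, decay_tau = 0.6,
                                noise_sd = 2, sample_interval = 0.05,
                                seed = NULL) {
  if (!is.numeric(rate) || rate < 0) abort_validation("rate must be >= 0 Hz")
  if (!is.numeric(duration) || duration <= 0) abort_validation("duration must be > 0 s")
  if (rise_tau >= decay_tau) abort_validation("rise_tau must be < decay_tau")
  if (sample_interval <= 0) abort_validation("sample_interval must be > 0 ms")
  if (duration * rate > 1e6) abort_validation("refusing to draw > 1e6 events (duration * rate too large)")

  if (!is.null(seed)) set.seed(derive_seed(seed, 2L))
  n <- ceiling(duration * 1000 / sample_interval)
  t_ms <- (seq_len(n) - 1) * sample_interval
  trace <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)

  n_ev <- stats::rpois(1, rate * duration)
  onsets <- sort(stats::runif(n_ev, 0, duration * 1000))
  amps <- rtnorm0(n_ev, amp_mean, amp_mean * amp_cv)

  # kernel long enough for the slow tail to die to < 1e-6 of peak
  k_len_ms <- decay_tau * 15
  k_t <- seq(0, k_len_ms, by = sample_interval)
  t_star <- log(decay_tau / rise_tau) * decay_tau * rise_tau / (decay_tau - rise_tau)
  s_peak <- exp(-t_star / decay_tau) - exp(-t_star / rise_tau)
  kernel <- (exp(-k_t / decay_tau) - exp(-k_t / rise_tau)) / s_peak

  for (e in seq_len(n_ev)) {
    i0 <- floor(onsets[e] / sample_interval) + 1
    idx <- i0:min(n, i0 + length(kernel) - 1)
    trace[idx] <- trace[idx] + amps[e] * kernel[seq_along(idx)]
  }

  samples <- tibble::tibble(t_ms = t_ms, `ch:im:sweep1` = trace)
  sweep_set(samples, sample_interval = sample_interval,
            channels = c(im = "pA"),
            meta = list(polarity = "inward, stored as positive magnitude",
                        truth = list(rate_hz = rate, amp_mean_pA = amp_mean,
                                     amp_cv = amp_cv, rise_tau_ms = rise_tau,
                                     decay_tau_ms = decay_tau,
                                     noise_sd_pA = noise_sd, seed = seed,
                                     events = tibble::tibble(onset_ms = onsets,
                                                             amplitude_pA = amps))))
}
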