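#' Detect miniature EPSCs in a continuous trace
#'
#' Threshold-crossing detection on the baseline-subtracted signal. The
#' baseline is a rolling median (robust to event overlap); the noise SD is
#' estimated robustly as `1.4826 * MAD` of the baseline-subtracted trace
#' (event samples are sparse, so the MAD tracks the noise, not the events).
#' A candidate event is a contiguous region above
#' `threshold_k * noise SD`; its amplitude is the regional peak. Candidates
#' below `min_amp` are dropped and events closer than `refractory` are
#' merged, keeping the larger peak. Kinetics (10-90% rise, decay tau) are
#' filled per event via [mini_kinetics()].
#'
#' Events are assumed positive-going (magnitude convention; see
#' [simulate_mini_trace()]).
#'
#' @param trace A single-channel current [sweep_set()].
#' @param threshold_k Detection threshold, multiples of noise SD (default 4).
#' @param min_amp Minimum amplitude, pA (default 10).
#' @param refractory Merge window, ms (default 5).
#' @param baseline_ms Rolling-median baseline window, ms (default 20).
#' @param channel,sweep Trace selection.
#' @return A tibble of class `mini_events` with columns `onset_ms`,
#'   `peak_ms`, `amplitude_pA`, `rise_10_90_ms`, `decay_tau_ms`, `fit_ok`;
#'   attributes `duration_s` and `noise_sd_pA`.
#' @export
detect_minis <- function(trace, threshold_k = 4, min_amp = 10, refractory = 5,
                         baseline_ms = 20, channel = "im", sweep = 1) {
  y <- sweep_trace(trace, channel, sweep)
  t_ms <- sweep_time(trace)
  si <- trace$sample_interval
  if (length(y) * si < 1000)
    abort_validation("trace shorter than 1 s; mini statistics need longer records")

  k <- max(3L, round(baseline_ms / si))
  if (k %% 2 == 0) k <- k + 1L
  baseline <- stats::runmed(y, k, endrule = "median")
  sig <- y - baseline
  noise_sd <- stats::mad(sig)
  if (noise_sd == 0) abort_validation("degenerate trace: zero noise SD")

  thr <- threshold_k * noise_sd
  above <- sig > thr
  if (!any(above)) return(empty_mini_events(t_ms, si, noise_sd))

  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L
  peak_idx <- mapply(function(s, e) s - 1L + which.max(sig[s:e]), starts, ends)
  amp <- sig[peak_idx]

  keep <- amp >= min_amp
  peak_idx <- peak_idx[keep]; amp <- amp[keep]; starts <- starts[keep]
  if (!length(peak_idx)) return(empty_mini_events(t_ms, si, noise_sd))

  # merge events closer than the refractory period, keeping the larger peak
  ord <- order(peak_idx)
  peak_idx <- peak_idx[ord]; amp <- amp[ord]; starts <- starts[ord]
  repeat {
    if (length(peak_idx) < 2) break
    gaps <- diff(peak_idx) * si
    close_pair <- which(gaps < refractory)
    if (!length(close_pair)) break
    i <- close_pair[1]; j <- i + 1
    drop <- if (amp[j] > amp[i]) i else j
    sel <- setdiff(seq_along(amp), drop)
    peak_idx <- peak_idx[sel]; amp <- amp[sel]; starts <- starts[sel]
  }

  events <- tibble::tibble(
    onset_ms = t_ms[starts],
    peak_ms = t_ms[peak_idx],
    amplitude_pA = amp)
  kin <- purrr::pmap_dfr(events, function(onset_ms, peak_ms, amplitude_pA) {
    mini_kinetics_core(t_ms, sig, si, onset_ms, peak_ms, amplitude_pA)
  })
  out <- dplyr::bind_cols(events, kin)
  structure(out, duration_s = length(y) * si / 1000, noise_sd_pA = noise_sd,
            class = c("mini_events", class(out)))
}

empty_mini_events <- function(t_ms, si, noise_sd) {
  out <- tibble::tibble(onset_ms = numeric(), peak_ms = numeric(),
                        amplitude_pA = numeric(), rise_10_90_ms = numeric(),
                        decay_tau_ms = numeric(), fit_ok = logical())
  structure(out, duration_s = length(t_ms) * si / 1000, noise_sd_pA = noise_sd,
            class = c("mini_events", class(out)))
}

#' Rise and decay kinetics of one miniature event
#'
#' The 10-90% rise time is measured on the rising limb between onset and
#' peak with linear interpolation between samples. The decay time constant
#' comes from a least-squares single-exponential fit over the segment from
#' 80% of the peak (past which the fast rising component has died away and
#' the event decays mono-exponentially) down to 10% of the peak. The window
#' is defined by peak fractions, not fixed lengths, so tau does not scale
#' with event size.
#'
#' @param trace A single-channel current [sweep_set()].
#' @param event One row of a `mini_events` tibble (or a list with
#'   `onset_ms`, `peak_ms`, `amplitude_pA`).
#' @inheritParams detect_minis
#' @return A one-row tibble: `rise_10_90_ms`, `decay_tau_ms`, `fit_ok`.
#' @export
mini_kinetics <- function(trace, event, baseline_ms = 20,
                          channel = "im", sweep = 1) {
  y <- sweep_trace(trace, channel, sweep)
  t_ms <- sweep_time(trace)
  si <- trace$sample_interval
  k <- max(3L, round(baseline_ms / si)); if (k %% 2 == 0) k <- k + 1L
  sig <- y - stats::runmed(y, k, endrule = "median")
  mini_kinetics_core(t_ms, sig, si, event$onset_ms, event$peak_ms,
                     event$amplitude_pA)
}

mini_kinetics_core <- function(t_ms, sig, si, onset_ms, peak_ms, amplitude_pA) {
  ip <- which.min(abs(t_ms - peak_ms))
  i0 <- max(1L, which.min(abs(t_ms - onset_ms)) - ceiling(2 / si))

  # rising limb: walk back from the peak to the last sample below 10%
  rise <- sig[i0:ip]
  tt <- t_ms[i0:ip]
  lo <- 0.1 * amplitude_pA; hi <- 0.9 * amplitude_pA
  t10 <- cross_time_up(tt, rise, lo)
  t90 <- cross_time_up(tt, rise, hi)
  rise_10_90 <- if (is.na(t10) || is.na(t90)) NA_real_ else max(t90 - t10, 0)

  # decay: 80% of peak down to 10% of peak. The first samples after the
  # peak still contain the (fast) rising component; by 80% of peak the
  # event is effectively single-exponential with the decay time constant.
  after <- sig[ip:length(sig)]
  start_off <- which(after <= 0.8 * amplitude_pA)
  istart <- if (length(start_off)) ip + start_off[1] - 1L else ip
  below <- which(after < 0.1 * amplitude_pA)
  iend <- if (length(below)) ip + below[1] - 1L else length(sig)
  fit <- if (iend > istart + 2) fit_exp_decay(t_ms[istart:iend], sig[istart:iend])
         else list(tau = NA_real_, ok = FALSE)

  tibble::tibble(rise_10_90_ms = rise_10_90,
                 decay_tau_ms = fit$tau,
                 fit_ok = isTRUE(fit$ok) && !is.na(rise_10_90))
}

# last upward crossing of `level` before the maximum, linearly interpolated
cross_time_up <- function(tt, yy, level) {
  im <- which.max(yy)
  below <- which(yy[seq_len(im)] < level)
  if (!length(below)) return(if (yy[1] >= level) tt[1] else NA_real_)
  i <- max(below)
  if (i == im) return(tt[im])
  # interpolate between samples i and i+1
  y0 <- yy[i]; y1 <- yy[i + 1]
  if (y1 == y0) return(tt[i + 1])
  tt[i] + (level - y0) / (y1 - y0) * (tt[i + 1] - tt[i])
}

#' Miniature event frequency
#'
#' @param events A `mini_events` tibble (or anything with `nrow()`).
#' @param duration Record duration, s; defaults to the `duration_s`
#'   attribute of `events`.
#' @return Frequency in Hz (`count / duration`).
#' @export
mini_frequency <- function(events, duration = NULL) {
  duration <- duration %||% attr(events, "duration_s")
  if (is.null(duration) || duration <= 0) abort_validation("duration must be > 0 s")
  nrow(events) / duration
}

#' Summarise detected minis the way the field reports them
#'
#' @param events A `mini_events` tibble.
#' @return One-row tibble: n, mean amplitude (pA), mean 10-90% rise (ms),
#'   mean decay tau (ms, fitted events only), frequency (Hz).
#' @export
summarize_minis <- function(events) {
  tibble::tibble(
    n_events = nrow(events),
    amplitude_pA = mean(events$amplitude_pA),
    rise_10_90_ms = mean(events$rise_10_90_ms, na.rm = TRUE),
    decay_tau_ms = mean(events$decay_tau_ms[events$fit_ok], na.rm = TRUE),
    frequency_hz = mini_frequency(events))
}
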