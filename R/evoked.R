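#' p/4 leak subtraction
#'
#' Removes linear (ohmic) leak and capacitive components using the
#' traditional p/4 protocol: four sweeps at one quarter of the test
#' stimulus amplitude accompany each test sweep, and the corrected trace is
#' `test - 4 * mean(quarter responses)`, sample-wise. Purely linear
#' responses cancel exactly; the nonlinear signal survives.
#'
#' @param sweeps A [sweep_set()] whose first sweep of `channel` is the test
#'   sweep and whose following four sweeps are the p/4 leak sweeps (or pass
#'   explicit indices).
#' @param channel Channel name (default `"im"`).
#' @param test_sweep,leak_sweeps Sweep indices (defaults 1 and 2:5).
#' @return A [sweep_set()] with a single corrected sweep of `channel`.
#' @export
p4_leak_subtract <- function(sweeps, channel = "im",
                             test_sweep = 1, leak_sweeps = 2:5) {
  cols <- sprintf("ch:%s:sweep%d", channel, leak_sweeps)
  missing_cols <- cols[!cols %in% names(sweeps$samples)]
  if (length(missing_cols))
    abort_validation(paste0("missing p/4 leak sweep(s): ",
                            paste(missing_cols, collapse = ", ")))
  test <- sweep_trace(sweeps, channel, test_sweep)
  leak_mean <- rowMeans(sapply(leak_sweeps, function(s) sweep_trace(sweeps, channel, s)))
  corrected <- test - 4 * leak_mean
  samples <- tibble::tibble(t_ms = sweep_time(sweeps))
  samples[[sprintf("ch:%s:sweep1", channel)]] <- corrected
  sweep_set(samples, sample_interval = sweeps$sample_interval,
            channels = sweeps$channels[channel],
            protocol = sweeps$protocol,
            meta = c(sweeps$meta, list(leak_subtracted = "p/4")))
}

#' Measure an evoked EPSC
#'
#' Baseline-subtracted peak measurement: the baseline is the mean over a
#' window ending `baseline_gap` before the stimulus; the peak is the signal
#' minimum (EPSCs are inward) over a window after the stimulus, excluding
#' the first `artifact_blank` ms (stimulus artifact). The amplitude is the
#' magnitude of peak minus baseline, reported in nA.
#'
#' @param sweep A [sweep_set()] with a current channel in pA.
#' @param stim_time Stimulus time, ms.
#' @param baseline_window,baseline_gap Baseline length and pre-stimulus
#'   gap, ms (defaults 5 and 0.5).
#' @param peak_window Peak-search window after the stimulus, ms (default 5).
#' @param artifact_blank Post-stimulus blanking, ms (default 0.3).
#' @param channel,sweep_idx Trace selection.
#' @return A one-row tibble of class `evoked_measure`: `stim_time_ms`,
#'   `baseline_pA`, `amplitude_nA`, `peak_time_ms`, `truncated` (peak at
#'   the window edge), `decay_tau_ms` (NA until [fit_evoked_decay()]).
#' @export
measure_epsc <- function(sweep, stim_time, baseline_window = 5,
                         baseline_gap = 0.5, peak_window = 5,
                         artifact_blank = 0.3, channel = "im", sweep_idx = 1) {
  y <- sweep_trace(sweep, channel, sweep_idx)
  t_ms <- sweep_time(sweep)
  b_idx <- t_ms >= (stim_time - baseline_gap - baseline_window) &
    t_ms < (stim_time - baseline_gap)
  p_idx <- t_ms >= (stim_time + artifact_blank) & t_ms < (stim_time + peak_window)
  if (!any(b_idx) || !any(p_idx))
    abort_validation("baseline or peak window lies outside the sweep")
  baseline <- mean(y[b_idx])
  seg <- y[p_idx]; seg_t <- t_ms[p_idx]
  ip <- which.min(seg)
  truncated <- ip == 1L || ip == length(seg)
  if (truncated)
    rlang::warn("peak at the edge of the search window; possible truncation",
                class = "calyxq_truncation_warning")
  out <- tibble::tibble(stim_time_ms = stim_time,
                        baseline_pA = baseline,
                        amplitude_nA = abs(seg[ip] - baseline) / 1000,
                        peak_time_ms = seg_t[ip],
                        truncated = truncated,
                        decay_tau_ms = NA_real_)
  structure(out, class = c("evoked_measure", class(out)))
}

#' Fit the single-exponential decay of an evoked EPSC
#'
#' Least-squares single exponential on the decay limb, from 80% of the
#' EPSC peak (clear of the rising phase) to where the current has recovered
#' to 10% of its amplitude.
#'
#' @param sweep The [sweep_set()] the measure came from.
#' @param measure An `evoked_measure` row from [measure_epsc()].
#' @inheritParams measure_epsc
#' @return `measure` with `decay_tau_ms` filled (NA, with a warning, if the
#'   fit fails).
#' @export
fit_evoked_decay <- function(sweep, measure, channel = "im", sweep_idx = 1) {
  if (measure$amplitude_nA <= 0)
    abort_validation("cannot fit decay of a zero-amplitude EPSC")
  y <- sweep_trace(sweep, channel, sweep_idx)
  t_ms <- sweep_time(sweep)
  ip <- which.min(abs(t_ms - measure$peak_time_ms))
  # magnitude relative to baseline; decays from the peak toward 0. As for
  # minis, the fit runs from 80% of the peak (clear of any residual rising
  # component) down to 10%.
  mag <- (measure$baseline_pA - y) / 1000
  after <- mag[ip:length(mag)]
  start_off <- which(after <= 0.8 * measure$amplitude_nA)
  istart <- if (length(start_off)) ip + start_off[1] - 1L else ip
  below <- which(after < 0.1 * measure$amplitude_nA)
  iend <- if (length(below)) ip + below[1] - 1L else length(mag)
  fit <- fit_exp_decay(t_ms[istart:iend], mag[istart:iend])
  if (!fit$ok)
    rlang::warn("decay fit did not converge; decay_tau_ms left NA",
                class = "calyxq_fit_warning")
  measure$decay_tau_ms <- fit$tau
  measure
}

#' Paired-pulse ratio
#'
#' `PPR = A2 / A1`. When measured from a two-pulse sweep, use
#' [measure_ppr()], which takes the second amplitude from a short baseline
#' immediately before pulse 2 (residual-current subtraction).
#'
#' @param a1,a2 First and second EPSC amplitudes (same units).
#' @return Dimensionless ratio.
#' @export
paired_pulse_ratio <- function(a1, a2) {
  if (any(a1 <= 0)) abort_validation("a1 must be > 0")
  if (any(a2 < 0)) abort_validation("a2 must be >= 0")
  a2 / a1
}

#' @rdname paired_pulse_ratio
#' @param sweep A [sweep_set()].
#' @param stim_times Two stimulus times, ms.
#' @param ... Passed to [measure_epsc()].
#' @export
measure_ppr <- function(sweep, stim_times, ...) {
  if (length(stim_times) != 2) abort_validation("stim_times must have length 2")
  m1 <- measure_epsc(sweep, stim_times[1], ...)
  # pulse-2 baseline: 0.5 ms immediately before pulse 2, so the residual
  # decaying current of pulse 1 is subtracted rather than extrapolated
  m2 <- measure_epsc(sweep, stim_times[2], baseline_window = 0.5,
                     baseline_gap = 0, ...)
  tibble::tibble(a1_nA = m1$amplitude_nA, a2_nA = m2$amplitude_nA,
                 ppr = paired_pulse_ratio(m1$amplitude_nA, m2$amplitude_nA))
}

#' Post-tetanic potentiation analysis
#'
#' Compares evoked amplitudes before and after a tetanus (100 Hz, 3 s in
#' the standard protocol). Reports group means, the potentiation ratio
#' `post_mean / pre_mean`, the post-tetanus time course normalized to the
#' pre-tetanus mean, and a paired t-test when the measurements pair up.
#'
#' @param pre,post Numeric amplitude vectors (>= 3 each), nA.
#' @param post_times Optional times of the post measurements, s.
#' @param paired Use a paired comparison (default when lengths match).
#' @return A `ptp_result` object; see [tidy.ptp_result()].
#' @export
ptp_analysis <- function(pre, post, post_times = NULL,
                         paired = length(pre) == length(post)) {
  if (length(pre) < 3 || length(post) < 3)
    abort_validation("need >= 3 pre and >= 3 post measurements")
  if (mean(pre) <= 0) abort_validation("pre-tetanus mean must be > 0")
  cmp <- compare_groups(post, pre, paired = paired, method = "t")
  structure(
    list(pre_mean = mean(pre), post_mean = mean(post),
         pre_sem = stats::sd(pre) / sqrt(length(pre)),
         post_sem = stats::sd(post) / sqrt(length(post)),
         ratio = mean(post) / mean(pre),
         p_value = cmp$p_value, paired = paired,
         post_timecourse = tibble::tibble(
           time_s = post_times %||% seq_along(post),
           normalized = post / mean(pre))),
    class = "ptp_result")
}

#' @export
print.ptp_result <- function(x, ...) {
  cat(sprintf("<ptp_result> pre %.3g, post %.3g (ratio %.3f), %s p = %.3g\n",
              x$pre_mean, x$post_mean, x$ratio,
              if (x$paired) "paired t" else "unpaired t", x$p_value))
  invisible(x)
}
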