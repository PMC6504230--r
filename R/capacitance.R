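#' Measure the capacitance jump of one depolarizing pulse
#'
#' `delta_cm` is the mean capacitance over a post-pulse window minus the
#' mean over a pre-pulse window. The first `artifact_skip` ms after the
#' pulse are excluded (conductance transients corrupt the capacitance
#' estimate there), so the post window is
#' `[pulse_end + artifact_skip, pulse_end + artifact_skip + post_window)`.
#' Ongoing endocytosis biases the measurement low by the window average of
#' `exp(-t/tau)`; with tau around 20 s and the default windows the bias is
#' well under 1%.
#'
#' @param sweep A [sweep_set()] with a `cm` channel (pF) and the pulse
#'   geometry in its protocol.
#' @param pulse_idx Which pulse (1-based; also selects the sweep for
#'   single-pulse families).
#' @param artifact_skip Post-pulse exclusion, ms (default 50).
#' @param pre_window,post_window Measurement windows, ms (defaults 50, 100).
#' @param sweep_idx Sweep holding the pulse (defaults to `pulse_idx` when
#'   the bundle has one sweep per pulse, else 1).
#' @return A one-row tibble of class `cap_pulse_result`:
#'   `pulse_duration_ms`, `delta_cm_fF`, `q_ica_pC`, `q_ica_density_pC_pF`,
#'   `resting_cm_pF`.
#' @export
measure_delta_cm <- function(sweep, pulse_idx = 1, artifact_skip = 50,
                             pre_window = 50, post_window = 100,
                             sweep_idx = NULL) {
  pt <- sweep$protocol$pulse_times_ms
  pd <- sweep$protocol$pulse_durations_ms
  if (is.null(pt) || is.null(pd))
    abort_validation("protocol must carry pulse_times_ms and pulse_durations_ms")
  multi_sweep <- n_sweeps(sweep, "cm") > 1
  sweep_idx <- sweep_idx %||% (if (multi_sweep) pulse_idx else 1L)
  p_start <- pt[min(pulse_idx, length(pt))]
  p_dur <- pd[min(pulse_idx, length(pd))]
  p_end <- p_start + p_dur

  # inside a multi-pulse sweep the post window must not reach the next pulse
  if (!multi_sweep && pulse_idx < length(pt)) {
    next_start <- pt[pulse_idx + 1]
    if (p_end + artifact_skip + post_window > next_start)
      abort_validation("post window overlaps the next pulse; shrink post_window")
  }

  t_ms <- sweep_time(sweep)
  cm <- sweep_trace(sweep, "cm", sweep_idx)
  pre_idx <- t_ms >= (p_start - pre_window) & t_ms < p_start
  post_idx <- t_ms >= (p_end + artifact_skip) &
    t_ms < (p_end + artifact_skip + post_window)
  if (!any(pre_idx) || !any(post_idx))
    abort_validation("measurement window lies outside the sweep")

  delta_fF <- (mean(cm[post_idx]) - mean(cm[pre_idx])) * 1000
  resting_idx <- t_ms < pt[1]
  resting <- mean(cm[resting_idx])

  q <- integrate_ca_charge(sweep, pulse_idx, pre_window = pre_window,
                           sweep_idx = sweep_idx, resting_cm = resting)
  out <- tibble::tibble(pulse_duration_ms = p_dur,
                        delta_cm_fF = delta_fF,
                        q_ica_pC = q$q_ica_pC,
                        q_ica_density_pC_pF = q$q_ica_density_pC_pF,
                        resting_cm_pF = resting)
  structure(out, class = c("cap_pulse_result", class(out)))
}

#' Integrate the calcium charge of one pulse
#'
#' Trapezoidal integral of the baseline-subtracted current over the pulse,
#' reported as a magnitude in pC, plus its density relative to the resting
#' capacitance (pC/pF). Baseline subtraction makes the charge invariant to
#' holding-current offsets. Apply [p4_leak_subtract()] first when the
#' current channel still contains linear leak.
#'
#' @inheritParams measure_delta_cm
#' @param resting_cm Resting capacitance, pF; taken from the sweep's first
#'   baseline when NULL.
#' @return A list with `q_ica_pC` and `q_ica_density_pC_pF`.
#' @export
integrate_ca_charge <- function(sweep, pulse_idx = 1, pre_window = 50,
                                sweep_idx = NULL, resting_cm = NULL) {
  pt <- sweep$protocol$pulse_times_ms
  pd <- sweep$protocol$pulse_durations_ms
  if (is.null(pt)) abort_validation("protocol must carry pulse_times_ms")
  if (!"im" %in% names(sweep$channels))
    abort_validation("no current channel `im` in this bundle")
  multi_sweep <- n_sweeps(sweep, "im") > 1
  sweep_idx <- sweep_idx %||% (if (multi_sweep) pulse_idx else 1L)
  p_start <- pt[min(pulse_idx, length(pt))]
  p_dur <- pd[min(pulse_idx, length(pd))]

  t_ms <- sweep_time(sweep)
  si <- sweep$sample_interval
  im <- sweep_trace(sweep, "im", sweep_idx)
  base_idx <- t_ms >= (p_start - pre_window) & t_ms < p_start
  # one sample of margin on each side so the trapezoid integrates the
  # rising and falling edges of a step-like current exactly
  in_idx <- t_ms >= (p_start - si) & t_ms <= (p_start + p_dur)
  if (!any(base_idx) || sum(in_idx) < 2)
    abort_validation("pulse window lies outside the sweep")
  baseline <- mean(im[base_idx])
  q_fc <- pracma::trapz(t_ms[in_idx], im[in_idx] - baseline)  # pA * ms = fC
  q_pc <- abs(q_fc) / 1000
  if (is.null(resting_cm)) {
    if (!"cm" %in% names(sweep$channels))
      abort_validation("resting_cm unavailable: no capacitance channel and none supplied")
    resting_cm <- mean(sweep_trace(sweep, "cm", sweep_idx)[t_ms < pt[1]])
  }
  list(q_ica_pC = q_pc, q_ica_density_pC_pF = q_pc / resting_cm)
}

#' Analyze a 20-pulse depolarizing train
#'
#' Per-pulse capacitance jumps for the pool-depleting protocol (20 pulses,
#' 10 ms, 10 Hz), their accumulated sum, and the cumulative time course
#' normalized to the first jump. Between pulses the measurement geometry
#' shrinks: after the 50-ms artifact skip only 40 ms remain before the next
#' pre-pulse window, so the post (and pre) windows are 40 ms.
#'
#' @param sweep A [sweep_set()] from the train protocol (20 pulses at
#'   100-ms spacing).
#' @param artifact_skip Post-pulse exclusion, ms (default 50).
#' @param window In-train measurement window, ms (default 40).
#' @param fit_endo Also fit the post-train endocytosis decay (default TRUE
#'   when the trace extends well past the train).
#' @return A `cap_train_result`: list with `per_pulse` tibble,
#'   `sigma_delta_cm_fF`, `normalized_timecourse` tibble, `resting_cm_pF`,
#'   `endo_tau_s` (NA unless fitted).
#' @export
analyze_cap_train <- function(sweep, artifact_skip = 50, window = 40,
                              fit_endo = NULL) {
  pt <- sweep$protocol$pulse_times_ms
  if (length(pt) < 20) abort_validation("train protocol requires 20 pulses")
  per <- purrr::map_dfr(seq_along(pt), function(j) {
    measure_delta_cm(sweep, j, artifact_skip = artifact_skip,
                     pre_window = window, post_window = window, sweep_idx = 1)
  })
  if (per$delta_cm_fF[1] <= 0)
    abort_validation("normalization undefined: first capacitance jump is not positive")
  sigma <- sum(per$delta_cm_fF)
  tc <- tibble::tibble(
    pulse = seq_along(pt),
    time_s = (pt + sweep$protocol$pulse_durations_ms) / 1000,
    cumulative_fF = cumsum(per$delta_cm_fF),
    normalized = cumsum(per$delta_cm_fF) / per$delta_cm_fF[1])

  t_end <- max(sweep_time(sweep))
  last_pulse_end <- pt[length(pt)] + sweep$protocol$pulse_durations_ms[length(pt)]
  do_endo <- fit_endo %||% ((t_end - last_pulse_end) > 20000)
  endo <- if (do_endo) fit_endocytosis(sweep, after_ms = last_pulse_end + artifact_skip)
          else NA_real_

  structure(list(per_pulse = per,
                 sigma_delta_cm_fF = sigma,
                 normalized_timecourse = tc,
                 resting_cm_pF = per$resting_cm_pF[1],
                 endo_tau_s = endo),
            class = "cap_train_result")
}

#' @export
print.cap_train_result <- function(x, ...) {
  cat(sprintf("<cap_train_result> %d pulses, sigma delta Cm = %.1f fF, resting Cm = %.2f pF",
              nrow(x$per_pulse), x$sigma_delta_cm_fF, x$resting_cm_pF))
  if (is.finite(x$endo_tau_s)) cat(sprintf(", endocytosis tau = %.1f s", x$endo_tau_s))
  cat("\n")
  invisible(x)
}

#' Fit the endocytosis time constant
#'
#' Single-exponential least-squares fit (with floor) of the capacitance
#' decay from its post-stimulus maximum back toward baseline. The trace
#' should extend for at least about two expected time constants.
#'
#' @param sweep A [sweep_set()] with a `cm` channel.
#' @param after_ms Start of the search for the decay maximum, ms.
#' @param sweep_idx Sweep index.
#' @return Endocytosis time constant in seconds; NA (with a warning) when
#'   the trace does not decay.
#' @export
fit_endocytosis <- function(sweep, after_ms, sweep_idx = 1) {
  t_ms <- sweep_time(sweep)
  cm <- sweep_trace(sweep, "cm", sweep_idx)
  sel <- t_ms >= after_ms
  if (sum(sel) < 10) abort_validation("too little trace after `after_ms`")
  tt <- t_ms[sel]; yy <- cm[sel]
  im <- which.max(yy)
  tt <- tt[im:length(tt)]; yy <- yy[im:length(yy)]
  if (length(yy) < 10 || yy[1] - min(yy) <= 0 ||
      stats::cor(tt, yy) > -0.2) {
    rlang::warn("capacitance does not decay after the stimulus; endo tau left NA",
                class = "calyxq_fit_warning")
    return(NA_real_)
  }
  fit <- fit_exp_decay(tt, yy, with_offset = TRUE)
  if (!fit$ok) {
    rlang::warn("endocytosis fit did not converge; endo tau left NA",
                class = "calyxq_fit_warning")
    return(NA_real_)
  }
  fit$tau / 1000
}

#' Current-voltage relationship of a sweep family
#'
#' One sweep per step potential: the peak current is the signed extremum of
#' the baseline-subtracted current during the step; `v_at_peak` is the
#' potential of the most-negative (largest inward) current.
#'
#' @param family A [sweep_set()] from [simulate_iv_family()] or equivalent,
#'   with `step_mv` (one per sweep) in its protocol.
#' @return A tibble of class `iv_curve` (`step_mv`, `peak_pA`) with
#'   attribute `v_at_peak_mV`; retrieve it with [v_at_peak()].
#' @export
iv_curve <- function(family) {
  v <- family$protocol$step_mv
  if (is.null(v) || length(v) != n_sweeps(family, "im"))
    abort_validation("protocol step_mv must list one potential per sweep")
  if (anyDuplicated(v)) abort_validation("duplicate step potentials")
  t_ms <- sweep_time(family)
  p_start <- family$protocol$pulse_times_ms[1]
  p_dur <- family$protocol$pulse_durations_ms[1]
  in_idx <- t_ms >= p_start & t_ms < p_start + p_dur
  base_idx <- t_ms < p_start
  peaks <- vapply(seq_along(v), function(s) {
    im <- sweep_trace(family, "im", s)
    seg <- im[in_idx] - mean(im[base_idx])
    seg[which.max(abs(seg))]
  }, numeric(1))
  out <- tibble::tibble(step_mv = v, peak_pA = peaks)
  structure(out, v_at_peak_mV = v[which.min(peaks)],
            class = c("iv_curve", class(out)))
}

#' @rdname iv_curve
#' @param x An `iv_curve`.
#' @export
v_at_peak <- function(x) attr(x, "v_at_peak_mV")

#' @export
autoplot.iv_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$step_mv, .data$peak_pA)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = v_at_peak(object), linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "step potential (mV)", y = "peak current (pA)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cap_train_result <- function(object, ...) {
  ggplot2::ggplot(object$normalized_timecourse,
                  ggplot2::aes(.data$time_s, .data$normalized)) +
    ggplot2::geom_step() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (s)",
                  y = "cumulative capacitance jump (norm. to first)") +
    ggplot2::theme_minimal()
}
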