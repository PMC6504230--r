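#' Simulate presynaptic capacitance sweeps
#'
#' Generates the two-channel sweeps used for exocytosis analysis: a
#' capacitance channel `cm` (pF) showing a step jump at the end of each
#' depolarizing pulse that decays exponentially with the endocytosis time
#' constant, and a current channel `im` (pA) carrying the pulse-locked
#' calcium current from an instantaneous Boltzmann activation model,
#' `I = g_max * m_inf(V) * (V - E_rev)` with
#' `m_inf(V) = 1 / (1 + exp(-(V - V_half)/k))`.
#'
#' Two protocols are supported. `"single_pulses"` produces one sweep per
#' entry of `pulse_durations`, each with a single pulse starting at
#' `pre_ms`. `"train_20x10ms_10Hz"` produces one sweep with 20 pulses of
#' 10 ms at 100-ms spacing (the pool-depleting train protocol). A 50-ms
#' artifact window after each pulse is flagged in the protocol
#' (`artifact_ms`); by default the simulated capacitance is clean inside it,
#' but `artifact_amp_ff > 0` injects a fast decaying transient there so the
#' exclusion rule can be exercised.
#'
#' @param protocol `"single_pulses"` or `"train_20x10ms_10Hz"`.
#' @param resting_cm Resting membrane capacitance, pF.
#' @param pulse_durations Pulse durations, ms (single-pulse protocol).
#' @param delta_cm_per_pulse True capacitance jumps, fF; one per pulse
#'   (recycled). Default: duration-scaled jumps saturating near the 20-ms
#'   value for single pulses; a depressing train (steady level 20% of the
#'   first jump) for the train protocol.
#' @param endo_tau Endocytosis time constant, s.
#' @param ca_gmax,ca_vhalf,ca_slope,ca_erev Boltzmann calcium-channel model:
#'   maximal conductance (nS), half-activation (mV), slope factor (mV),
#'   reversal potential (mV).
#' @param holding_mv,step_mv Holding and pulse potentials, mV.
#' @param noise_sd_cm Capacitance noise SD, fF.
#' @param noise_sd_i Current noise SD, pA.
#' @param artifact_amp_ff Amplitude of the flagged post-pulse capacitance
#'   artifact, fF (decays with a 10-ms time constant; default 0).
#' @param pre_ms Baseline before the (first) pulse, ms.
#' @param post_ms Trace length after the last pulse, ms (use tens of
#'   seconds to fit endocytosis).
#' @param sample_interval Sampling interval, ms.
#' @param seed Integer seed.
#' @return A [sweep_set()] with channels `cm` (pF) and `im` (pA); ground
#'   truth in `meta$truth`.
#' @export
simulate_capacitance_sweeps <- function(protocol = c("single_pulses", "train_20x10ms_10Hz"),
                                        resting_cm = 20,
                                        pulse_durations = c(2, 3, 5, 10, 20),
                                        delta_cm_per_pulse = NULL,
                                        endo_tau = 19.5,
                                        ca_gmax = 12.5, ca_vhalf = -24,
                                        ca_slope = 6, ca_erev = 45,
                                        holding_mv = -80, step_mv = 0,
                                        noise_sd_cm = 0, noise_sd_i = 0,
                                        artifact_amp_ff = 0,
                                        pre_ms = 100, post_ms = 1000,
                                        sample_interval = 0.5, seed = NULL) {
  protocol <- match.arg(protocol)
  if (resting_cm <= 0) abort_validation("resting_cm must be > 0 pF")
  if (endo_tau <= 0) abort_validation("endo_tau must be > 0 s")
  if (any(pulse_durations <= 0)) abort_validation("pulse_durations must all be > 0 ms")
  if (!is.null(seed)) set.seed(derive_seed(seed, 3L))

  if (protocol == "train_20x10ms_10Hz") {
    n_pulses <- 20L
    durs <- rep(10, n_pulses)
    onsets <- pre_ms + (seq_len(n_pulses) - 1) * 100
    if (is.null(delta_cm_per_pulse)) {
      first <- 60
      delta_cm_per_pulse <- first * (0.2 + 0.8 * 0.75^(seq_len(n_pulses) - 1))
    }
    jumps <- rep_len(delta_cm_per_pulse, n_pulses)
    sweeps <- 1L
  } else {
    durs <- pulse_durations
    n_pulses <- length(durs)
    onsets <- rep(pre_ms, n_pulses)        # one pulse per sweep
    if (is.null(delta_cm_per_pulse))
      delta_cm_per_pulse <- 148 * (1 - exp(-durs / 8))  # saturating with duration
    jumps <- rep_len(delta_cm_per_pulse, n_pulses)
    sweeps <- n_pulses
  }
  if (any(onsets + durs > c(onsets[-1], Inf)[seq_len(n_pulses)]) && sweeps == 1L)
    abort_validation("overlapping pulses")

  t_end <- if (sweeps == 1L) onsets[n_pulses] + durs[n_pulses] + post_ms else
    pre_ms + max(durs) + post_ms
  t_ms <- seq(0, t_end, by = sample_interval)
  n <- length(t_ms)

  m_inf <- 1 / (1 + exp(-(step_mv - ca_vhalf) / ca_slope))
  i_pulse <- ca_gmax * m_inf * (step_mv - ca_erev)   # pA

  cols <- list(t_ms = t_ms)
  truth_jumps <- numeric(0)
  for (s in seq_len(sweeps)) {
    pul <- if (sweeps == 1L) seq_len(n_pulses) else s
    cm <- rep(resting_cm, n)
    im <- numeric(n)
    for (j in pul) {
      t_jump <- onsets[j] + durs[j]          # exocytosis completes at pulse end
      after <- t_ms >= t_jump
      cm[after] <- cm[after] + jumps[j] * 1e-3 *
        exp(-(t_ms[after] - t_jump) / (endo_tau * 1000))
      if (artifact_amp_ff > 0) {
        art <- t_ms >= t_jump & t_ms < t_jump + 50
        cm[art] <- cm[art] + artifact_amp_ff * 1e-3 * exp(-(t_ms[art] - t_jump) / 10)
      }
      during <- t_ms >= onsets[j] & t_ms < onsets[j] + durs[j]
      im[during] <- im[during] + i_pulse
    }
    if (noise_sd_cm > 0) cm <- cm + stats::rnorm(n, 0, noise_sd_cm * 1e-3)
    if (noise_sd_i > 0) im <- im + stats::rnorm(n, 0, noise_sd_i)
    cols[[sprintf("ch:cm:sweep%d", s)]] <- cm
    cols[[sprintf("ch:im:sweep%d", s)]] <- im
    truth_jumps <- c(truth_jumps, jumps[pul])
  }

  sweep_set(tibble::as_tibble(cols), sample_interval = sample_interval,
            channels = c(cm = "pF", im = "pA"),
            protocol = list(pulse_times_ms = onsets,
                            pulse_durations_ms = durs,
                            holding_mv = holding_mv, step_mv = step_mv,
                            artifact_ms = 50),
            meta = list(truth = list(protocol = protocol,
                                     resting_cm_pF = resting_cm,
                                     delta_cm_fF = jumps,
                                     endo_tau_s = endo_tau,
                                     i_pulse_pA = i_pulse,
                                     ca = list(gmax_nS = ca_gmax, vhalf_mV = ca_vhalf,
                                               slope_mV = ca_slope, erev_mV = ca_erev),
                                     seed = seed)))
}

#' Simulate a calcium-channel I-V sweep family
#'
#' One sweep per step potential: a 200-ms step from the holding potential,
#' with the steady calcium current of the instantaneous Boltzmann model
#' `I(V) = g_max * m_inf(V) * (V - E_rev)`. The defaults place the
#' most-negative current of the standard -80 to +60 mV (10-mV) grid at
#' -10 mV with a peak near -625 pA.
#'
#' @param v_steps Step potentials, mV.
#' @inheritParams simulate_capacitance_sweeps
#' @param step_dur Step duration, ms.
#' @return A [sweep_set()] with channel `im` (pA), one sweep per potential.
#' @export
simulate_iv_family <- function(v_steps = seq(-80, 60, by = 10),
                               ca_gmax = 12.5, ca_vhalf = -24,
                               ca_slope = 6, ca_erev = 45,
                               holding_mv = -80, step_dur = 200,
                               noise_sd_i = 0, pre_ms = 50, post_ms = 50,
                               sample_interval = 0.5, seed = NULL) {
  if (!length(v_steps)) abort_validation("v_steps must be non-empty")
  if (!is.null(seed)) set.seed(derive_seed(seed, 4L))
  t_ms <- seq(0, pre_ms + step_dur + post_ms, by = sample_interval)
  n <- length(t_ms)
  during <- t_ms >= pre_ms & t_ms < pre_ms + step_dur
  cols <- list(t_ms = t_ms)
  i_true <- numeric(length(v_steps))
  for (s in seq_along(v_steps)) {
    v <- v_steps[s]
    m_inf <- 1 / (1 + exp(-(v - ca_vhalf) / ca_slope))
    i_true[s] <- ca_gmax * m_inf * (v - ca_erev)
    im <- numeric(n)
    im[during] <- i_true[s]
    if (noise_sd_i > 0) im <- im + stats::rnorm(n, 0, noise_sd_i)
    cols[[sprintf("ch:im:sweep%d", s)]] <- im
  }
  sweep_set(tibble::as_tibble(cols), sample_interval = sample_interval,
            channels = c(im = "pA"),
            protocol = list(pulse_times_ms = pre_ms,
                            pulse_durations_ms = step_dur,
                            holding_mv = holding_mv, step_mv = v_steps),
            meta = list(truth = list(v_steps_mV = v_steps, i_steady_pA = i_true,
                                     ca = list(gmax_nS = ca_gmax, vhalf_mV = ca_vhalf,
                                               slope_mV = ca_slope, erev_mV = ca_erev),
                                     seed = seed)))
}
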