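#' Simulate an auditory brainstem response intensity series
#'
#' For each click intensity, builds the averaged scalp waveform as the sum
#' of five Gaussian waves plus averaging-reduced noise. At and above the
#' true threshold, wave w has amplitude
#' `max(0, wave_amp_at_90db[w] - growth_slope * (90 - I))` and latency
#' `wave_latencies[w] + latency_shift_per_db * (90 - I)`; below threshold
#' the response is noise only. The waveform is the mean of two independent
#' half-averages (each averaging `n_sweeps / 2` sweeps), which are returned
#' for reproducibility-based thresholding.
#'
#' @param intensities Click intensities, dB (descending 90..20 by 5).
#' @param wave_latencies Wave I-V latencies at 90 dB, ms, strictly increasing.
#' @param latency_shift_per_db Latency increase per dB below 90, ms/dB.
#' @param wave_amp_at_90db Wave I-V amplitudes at 90 dB, uV.
#' @param growth_slope Amplitude loss per dB below 90, uV/dB.
#' @param threshold_true True response threshold, dB.
#' @param wave_width Gaussian SD of each wave, ms.
#' @param noise_sd Single-sweep noise SD, uV.
#' @param n_sweeps Sweeps per average.
#' @param sample_interval Sampling interval, ms (0.04 = 40-us sampling).
#' @param window Recording window, ms.
#' @param seed Integer seed.
#' @return A list of `abr_recording` objects (fields `intensity`,
#'   `waveform` tibble with `t_ms`/`uv`, `n_sweeps`, `halves`, `truth`).
#' @export
simulate_abr <- function(intensities = seq(90, 20, by = -5),
                         wave_latencies = c(1.5, 2.5, 3.5, 4.5, 5.5),
                         latency_shift_per_db = 0.005,
                         wave_amp_at_90db = c(3.0, 2.5, 2.6, 2.2, 1.5),
                         growth_slope = 0.04,
                         threshold_true = 40,
                         wave_width = 0.2,
                         noise_sd = 4, n_sweeps = 512,
                         sample_interval = 0.04, window = 10,
                         seed = NULL) {
  if (any(diff(wave_latencies) <= 0))
    abort_validation("wave_latencies must be strictly increasing")
  if (any(intensities < 20 | intensities > 90))
    abort_validation("intensities must lie within [20, 90] dB")
  if (sample_interval <= 0) abort_validation("sample_interval must be > 0 ms")
  if (!is.null(seed)) set.seed(derive_seed(seed, 5L))

  t_ms <- seq(0, window, by = sample_interval)
  half_sd <- noise_sd / sqrt(n_sweeps / 2)

  lapply(intensities, function(intensity) {
    att <- 90 - intensity
    if (intensity >= threshold_true) {
      amps <- pmax(0, wave_amp_at_90db - growth_slope * att)
      lats <- wave_latencies + latency_shift_per_db * att
    } else {
      amps <- rep(0, length(wave_latencies))
      lats <- wave_latencies + latency_shift_per_db * att
    }
    clean <- rowSums(vapply(seq_along(amps), function(w) {
      amps[w] * exp(-((t_ms - lats[w])^2) / (2 * wave_width^2))
    }, numeric(length(t_ms))))
    ha <- clean + if (noise_sd > 0) stats::rnorm(length(t_ms), 0, half_sd) else 0
    hb <- clean + if (noise_sd > 0) stats::rnorm(length(t_ms), 0, half_sd) else 0
    structure(
      list(intensity = intensity,
           waveform = tibble::tibble(t_ms = t_ms, uv = (ha + hb) / 2),
           n_sweeps = n_sweeps,
           halves = list(a = ha, b = hb),
           truth = list(amplitudes_uV = amps, latencies_ms = lats,
                        threshold_true_dB = threshold_true,
                        clean = clean, seed = seed)),
      class = "abr_recording")
  })
}

#' @export
print.abr_recording <- function(x, ...) {
  cat("<abr_recording> ", x$intensity, " dB, ", nrow(x$waveform),
      " samples, ", x$n_sweeps, " sweeps\n", sep = "")
  invisible(x)
}

#' @export
autoplot.abr_recording <- function(object, waves = NULL, ...) {
  p <- ggplot2::ggplot(object$waveform, ggplot2::aes(.data$t_ms, .data$uv)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after click (ms)", y = expression(paste(mu, "V")),
                  title = paste0(object$intensity, " dB")) +
    ggplot2::theme_minimal()
  if (!is.null(waves)) {
    d <- tibble::as_tibble(waves)
    d <- d[!is.na(d$latency_ms), ]
    p <- p + ggplot2::geom_point(data = d,
                                 ggplot2::aes(.data$latency_ms, .data$peak_uv),
                                 colour = "red") +
      ggplot2::geom_text(data = d,
                         ggplot2::aes(.data$latency_ms, .data$peak_uv,
                                      label = .data$wave),
                         vjust = -0.8, colour = "red")
  }
  p
}
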