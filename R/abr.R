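#' Detect ABR waves I-V
#'
#' Finds the `n_waves` largest local maxima of the averaged waveform inside
#' the search window (default 0-6 ms, where the five canonical waves fall)
#' and orders them by latency. A sample qualifies as a peak only if it is
#' the maximum within +/- `merge_window` ms, so twin peaks closer than that
#' merge into one. Wave amplitude is peak minus the following trough (the
#' waveform minimum between this peak and the next wave, or the end of the
#' search window for the last wave); `baseline_to_peak` is available as an
#' alternative convention. Latency is the peak time.
#'
#' @param rec An `abr_recording` (see [simulate_abr()]), or any list with a
#'   `waveform` tibble (`t_ms`, `uv`).
#' @param search_window Two-element window, ms (default `c(0, 6)`).
#' @param n_waves Number of waves sought (default 5).
#' @param merge_window Peak dominance half-window, ms (default 0.2).
#' @param min_amp Peaks smaller than this (uV, peak-to-trough) are ignored
#'   (default 0: keep all).
#' @param amplitude_mode `"peak_to_trough"` or `"baseline_to_peak"`.
#' @return A tibble of class `abr_waveset` with one row per wave I-V:
#'   `wave`, `latency_ms`, `peak_uv`, `amplitude_uv`, `found`; attribute
#'   `complete` says whether all `n_waves` qualified.
#' @export
detect_waves <- function(rec, search_window = c(0, 6), n_waves = 5,
                         merge_window = 0.2, min_amp = 0,
                         amplitude_mode = c("peak_to_trough", "baseline_to_peak")) {
  amplitude_mode <- match.arg(amplitude_mode)
  wf <- rec$waveform
  sel <- wf$t_ms >= search_window[1] & wf$t_ms <= search_window[2]
  tt <- wf$t_ms[sel]; yy <- wf$uv[sel]
  n <- length(yy)
  k <- max(1L, round(merge_window / (tt[2] - tt[1])))

  # local maxima dominant over +/- merge_window
  is_peak <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - k); hi <- min(n, i + k)
    yy[i] == max(yy[lo:hi]) &&
      (i == 1L || yy[i] >= yy[i - 1]) && (i == n || yy[i] >= yy[i + 1]) &&
      yy[i] > min(yy[lo:hi])           # reject flat segments
  }, logical(1))
  cand <- which(is_peak)
  # a run of equal qualifying samples (plateau) counts once
  if (length(cand) > 1) cand <- cand[c(TRUE, diff(cand) > k)]

  if (length(cand) > n_waves)
    cand <- sort(cand[order(yy[cand], decreasing = TRUE)][seq_len(n_waves)])

  waves <- tibble::tibble(wave = c("I", "II", "III", "IV", "V")[seq_len(n_waves)],
                          latency_ms = NA_real_, peak_uv = NA_real_,
                          amplitude_uv = NA_real_, found = FALSE)
  if (length(cand)) {
    for (w in seq_along(cand)) {
      i <- cand[w]
      trough_end <- if (w < length(cand)) cand[w + 1] else n
      trough <- min(yy[i:trough_end])
      amp <- switch(amplitude_mode,
                    peak_to_trough = yy[i] - trough,
                    baseline_to_peak = yy[i])
      waves$latency_ms[w] <- tt[i]
      waves$peak_uv[w] <- yy[i]
      waves$amplitude_uv[w] <- amp
      waves$found[w] <- TRUE
    }
    if (min_amp > 0) {
      weak <- waves$found & waves$amplitude_uv < min_amp
      waves$found[weak] <- FALSE
      waves$latency_ms[weak] <- NA_real_
      waves$peak_uv[weak] <- NA_real_
      waves$amplitude_uv[weak] <- NA_real_
      keep <- waves$found
      waves[, c("latency_ms", "peak_uv", "amplitude_uv")] <-
        lapply(waves[, c("latency_ms", "peak_uv", "amplitude_uv")],
               function(col) c(col[keep], rep(NA_real_, sum(!keep))))
      waves$found <- c(rep(TRUE, sum(keep)), rep(FALSE, sum(!keep)))
    }
  }
  structure(waves, complete = sum(waves$found) == n_waves,
            intensity = rec$intensity %||% NA_real_,
            class = c("abr_waveset", class(waves)))
}

#' Inter-wave conduction time
#'
#' Latency difference between two detected waves, e.g. wave IV minus wave
#' II as the central conduction time.
#'
#' @param waves An `abr_waveset` from [detect_waves()].
#' @param from,to Wave labels (`"I"`..`"V"`) or indices.
#' @return Conduction time in ms.
#' @export
interwave_latency <- function(waves, from, to) {
  get_lat <- function(w) {
    row <- if (is.character(w)) which(waves$wave == w) else as.integer(w)
    if (!length(row) || !isTRUE(waves$found[row]))
      abort_validation(paste0("wave ", w, " not detected"))
    waves$latency_ms[row]
  }
  get_lat(to) - get_lat(from)
}

#' Estimate the ABR threshold of an intensity series
#'
#' Operationalizes "the lowest intensity producing a reproducible waveform"
#' with two criteria: `"amplitude"` (the largest detected wave amplitude
#' exceeds `k` times the noise SD of the pre-response segment) or
#' `"correlation"` (Pearson correlation of the two replicate half-averages
#' exceeds `r_min`). The threshold is the lowest intensity at which the
#' criterion passes there and at every higher tested intensity.
#'
#' Both criteria are evaluated on a matched-filter-smoothed copy of the
#' recording (Gaussian kernel, `smooth_ms` SD, matched to the ~0.2-ms ABR
#' wave width): smoothing leaves wave peaks nearly intact while shrinking
#' the broadband noise several-fold, which is what separates a reproducible
#' waveform from averaged noise at the 40-us sampling of these recordings.
#' The amplitude criterion compares the largest wave peak above the
#' pre-response mean (baseline-to-peak, regardless of the reporting
#' convention) with `k` times the smoothed pre-response noise SD.
#'
#' @param recs List of `abr_recording` objects (descending intensities).
#' @param criterion `"amplitude"` (default) or `"correlation"`.
#' @param k Amplitude criterion multiplier (default 3).
#' @param r_min Correlation criterion cutoff (default 0.5).
#' @param noise_window Pre-response segment for the noise SD, ms
#'   (default `c(0, 1)`, before wave I).
#' @param smooth_ms Matched-filter Gaussian SD, ms (default 0.15).
#' @param ... Passed to [detect_waves()].
#' @return Threshold in dB, or `NA` (with attribute
#'   `no_response = TRUE`) when no tested intensity passes, meaning "no
#'   response at or below the maximum tested intensity".
#' @export
estimate_threshold <- function(recs, criterion = c("amplitude", "correlation"),
                               k = 3, r_min = 0.5, noise_window = c(0, 1),
                               smooth_ms = 0.15, ...) {
  criterion <- match.arg(criterion)
  ints <- vapply(recs, function(r) r$intensity, numeric(1))
  ord <- order(ints, decreasing = TRUE)
  recs <- recs[ord]; ints <- ints[ord]
  passes <- vapply(recs, function(rec) {
    si <- rec$waveform$t_ms[2] - rec$waveform$t_ms[1]
    if (criterion == "amplitude") {
      sm <- rec
      sm$waveform$uv <- gaussian_smooth(rec$waveform$uv, si, smooth_ms)
      noise_sel <- rec$waveform$t_ms >= noise_window[1] &
        rec$waveform$t_ms < noise_window[2]
      noise_raw <- rec$waveform$uv[noise_sel]
      # averaged noise is white at this sampling, so the smoothed-noise SD
      # is the raw SD scaled by the kernel L2 norm; estimating the raw SD
      # uses every pre-response sample, which keeps the estimate stable on
      # the short (1 ms) segment available before wave I
      noise_sd_sm <- stats::sd(noise_raw) * kernel_l2(si, smooth_ms)
      waves <- detect_waves(sm, ...)
      peaks <- waves$peak_uv[waves$found] - mean(noise_raw)
      length(peaks) > 0 && max(peaks) > k * noise_sd_sm
    } else {
      if (is.null(rec$halves))
        abort_validation("correlation criterion needs replicate half-averages")
      stats::cor(gaussian_smooth(rec$halves$a, si, smooth_ms),
                 gaussian_smooth(rec$halves$b, si, smooth_ms)) > r_min
    }
  }, logical(1))
  # lowest intensity passing with all higher intensities also passing
  run_ok <- cumprod(passes) == 1
  if (!any(run_ok))
    return(structure(NA_real_, no_response = TRUE))
  ints[max(which(run_ok))]
}

kernel_l2 <- function(si, sd_ms) {
  if (sd_ms <= 0) return(1)
  half <- max(1L, ceiling(3 * sd_ms / si))
  kern <- exp(-((-half:half) * si)^2 / (2 * sd_ms^2))
  kern <- kern / sum(kern)
  sqrt(sum(kern^2))
}

# Gaussian smoothing by direct convolution, edges renormalised
gaussian_smooth <- function(y, si, sd_ms) {
  if (sd_ms <= 0) return(y)
  half <- max(1L, ceiling(3 * sd_ms / si))
  kt <- (-half:half) * si
  kern <- exp(-kt^2 / (2 * sd_ms^2))
  kern <- kern / sum(kern)
  n <- length(y)
  padded <- c(rep(y[1], half), y, rep(y[n], half))
  out <- stats::filter(padded, kern, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' @export
print.abr_waveset <- function(x, ...) {
  cat("<abr_waveset>",
      if (!is.na(attr(x, "intensity"))) paste0(" ", attr(x, "intensity"), " dB"),
      if (!attr(x, "complete")) " (partial)", "\n", sep = "")
  NextMethod()
}
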