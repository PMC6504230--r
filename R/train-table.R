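#' Per-stimulus evoked-amplitude table
#'
#' Holds the ordered evoked EPSC amplitudes `A_n` of a stimulus train, the
#' input to the EQ and SMN pool estimators. Amplitudes are magnitudes in nA
#' (EPSCs are inward currents; the field reports them as positive nA).
#'
#' @param amplitudes Numeric vector of per-stimulus amplitudes (nA, >= 0).
#' @param freq Stimulation frequency in Hz.
#' @param stimulus_times Optional stimulus times in ms (default a regular
#'   grid at `freq` starting at 0); must be strictly increasing.
#' @param meta Free-form named list (simulators store truth here).
#' @return A tibble of class `train_measurement` with columns `stimulus`,
#'   `time_ms`, `amplitude_nA`, and attributes `freq_hz` and `meta`.
#' @export
train_measurement <- function(amplitudes, freq, stimulus_times = NULL, meta = list()) {
  if (!is.numeric(amplitudes) || !length(amplitudes) || anyNA(amplitudes))
    abort_validation("amplitudes must be a non-empty numeric vector")
  if (any(amplitudes < 0)) abort_validation("amplitudes must be >= 0 (magnitudes, nA)")
  if (!is.numeric(freq) || length(freq) != 1 || freq <= 0)
    abort_validation("freq must be a single positive number (Hz)")
  n <- length(amplitudes)
  if (is.null(stimulus_times)) stimulus_times <- (seq_len(n) - 1) * 1000 / freq
  if (length(stimulus_times) != n)
    abort_validation("stimulus_times and amplitudes must have equal length")
  if (any(diff(stimulus_times) <= 0))
    abort_validation("stimulus_times must be strictly increasing")
  out <- tibble::tibble(stimulus = seq_len(n),
                        time_ms = as.numeric(stimulus_times),
                        amplitude_nA = as.numeric(amplitudes))
  structure(out, freq_hz = freq, meta = meta,
            class = c("train_measurement", class(out)))
}

train_freq <- function(train) attr(train, "freq_hz")
train_meta <- function(train) attr(train, "meta") %||% list()

as_train_measurement <- function(x) {
  if (inherits(x, "train_measurement")) return(x)
  abort_validation("expected a train_measurement")
}

#' Read and write train tables
#'
#' CSV dialect: columns `stimulus`, `time_ms`, `amplitude_nA`; an optional
#' JSON sidecar (`<path minus .csv>.meta.json`) carries `freq_hz` and
#' metadata. Without a sidecar the frequency is inferred from the median
#' inter-stimulus interval.
#'
#' @param path CSV path.
#' @return `read_train_table()` returns a [train_measurement()].
#' @export
read_train_table <- function(path) {
  if (!file.exists(path)) abort_validation(paste0("no such file: ", path))
  tab <- read_numeric_csv(path)
  need <- c("stimulus", "time_ms", "amplitude_nA")
  if (!all(need %in% names(tab)))
    abort_validation(paste0("train table must have columns: ", paste(need, collapse = ", ")))
  side <- sidecar_path(path)
  meta <- list(); freq <- NULL
  if (file.exists(side)) {
    sj <- jsonlite::read_json(side, simplifyVector = TRUE)
    freq <- sj$freq_hz
    meta <- as.list(sj$meta %||% list())
  }
  if (is.null(freq)) freq <- 1000 / stats::median(diff(tab$time_ms))
  train_measurement(tab$amplitude_nA, freq = freq,
                    stimulus_times = tab$time_ms, meta = meta)
}

#' @rdname read_train_table
#' @param train A `train_measurement`.
#' @export
write_train_table <- function(train, path) {
  train <- as_train_measurement(train)
  write_numeric_csv(tibble::as_tibble(train), path)
  jsonlite::write_json(list(freq_hz = train_freq(train), meta = train_meta(train)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
autoplot.train_measurement <- function(object, normalized = FALSE, ...) {
  d <- tibble::as_tibble(object)
  if (normalized) d$amplitude_nA <- d$amplitude_nA / d$amplitude_nA[1]
  ggplot2::ggplot(d, ggplot2::aes(.data$stimulus, .data$amplitude_nA)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "stimulus number",
                  y = if (normalized) expression(A[n] / A[1]) else "eEPSC amplitude (nA)") +
    ggplot2::theme_minimal()
}
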