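#' Multi-sweep, multi-channel recording container
#'
#' A `sweep_set` holds uniformly sampled traces from one or more sweeps and
#' channels, together with the stimulus protocol and free-form metadata.
#' Samples live in a wide tibble whose first column is `t_ms` and whose
#' remaining columns are named `ch:<channel>:sweep<k>`; this matches the
#' on-disk CSV layout one-for-one, so bundles written with
#' [write_sweepset()] diff cleanly under version control.
#'
#' Channel units are restricted to `pA` (currents), `pF` (capacitance),
#' `mV` (potentials) and `uV` (far-field potentials; `"µV"` is accepted
#' and normalised to `uV`). Currents are stored signed (inward negative);
#' analysis functions report magnitudes, with polarity noted in metadata.
#'
#' @param samples Tibble/data frame: `t_ms` plus `ch:<name>:sweep<k>` columns.
#' @param sample_interval Sampling interval in ms.
#' @param channels Named character vector of units, e.g. `c(im = "pA")`.
#' @param protocol List of stimulus geometry: typically `stim_times_ms`,
#'   `pulse_durations_ms`, `holding_mv`, `step_mv`, `artifact_ms`.
#'   Times are in ms, 0-based at sweep start; windows are half-open `[t0, t1)`.
#' @param meta Free-form named list; simulators store ground truth under
#'   `meta$truth`.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(samples, sample_interval, channels,
                      protocol = list(), meta = list()) {
  samples <- tibble::as_tibble(samples)
  names(channels) <- names(channels) %||% character()
  channels[] <- sub("µV", "uV", channels, fixed = TRUE)
  x <- structure(
    list(samples = samples,
         sample_interval = as.numeric(sample_interval),
         channels = channels,
         protocol = protocol,
         meta = meta),
    class = "sweep_set")
  validate_sweep_set(x)
}

ALLOWED_UNITS <- c("pA", "pF", "mV", "uV")

#' @rdname sweep_set
#' @param x A `sweep_set`.
#' @export
validate_sweep_set <- function(x) {
  s <- x$samples
  if (ncol(s) < 2 || names(s)[1] != "t_ms")
    abort_validation("sweep_set samples must have `t_ms` as the first column plus at least one trace column")
  trace_cols <- names(s)[-1]
  bad <- trace_cols[!grepl("^ch:[^:]+:sweep[0-9]+$", trace_cols)]
  if (length(bad))
    abort_validation(paste0("malformed trace column name(s): ", paste(bad, collapse = ", ")))
  if (!is.numeric(x$sample_interval) || length(x$sample_interval) != 1 ||
      !is.finite(x$sample_interval) || x$sample_interval <= 0)
    abort_validation("sample_interval must be a single positive number (ms)")
  ch_in_cols <- unique(sub("^ch:([^:]+):sweep[0-9]+$", "\\1", trace_cols))
  if (!all(ch_in_cols %in% names(x$channels)))
    abort_validation("every trace column's channel must be declared in `channels`")
  if (!all(x$channels %in% ALLOWED_UNITS))
    abort_validation(paste0("channel units must be one of: ", paste(ALLOWED_UNITS, collapse = ", ")))
  if (anyNA(s)) abort_validation("samples contain missing values")
  t0 <- s$t_ms[1]; t1 <- s$t_ms[nrow(s)]
  pt <- c(x$protocol$stim_times_ms, x$protocol$pulse_times_ms)
  if (length(pt) && (any(pt < t0) || any(pt > t1)))
    abort_validation("protocol stimulus/pulse times fall outside the sweep window")
  x
}

#' @export
print.sweep_set <- function(x, ...) {
  cat("<sweep_set> ", nrow(x$samples), " samples @ ", x$sample_interval,
      " ms (", round(diff(range(x$samples$t_ms)) / 1000, 3), " s)\n", sep = "")
  cat("  channels: ",
      paste(sprintf("%s [%s]", names(x$channels), x$channels), collapse = ", "),
      "; sweeps: ", n_sweeps(x), "\n", sep = "")
  if (length(x$protocol))
    cat("  protocol: ", paste(names(x$protocol), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Accessors for sweep_set traces
#'
#' @param x A `sweep_set`.
#' @param channel Channel name.
#' @param sweep Sweep index (1-based).
#' @return `sweep_trace()` returns the numeric sample vector; `sweep_time()`
#'   the time base in ms; `n_sweeps()` the number of sweeps of a channel.
#' @export
sweep_trace <- function(x, channel, sweep = 1) {
  col <- sprintf("ch:%s:sweep%d", channel, sweep)
  if (!col %in% names(x$samples))
    abort_validation(paste0("no such trace column: ", col))
  x$samples[[col]]
}

#' @rdname sweep_trace
#' @export
sweep_time <- function(x) x$samples$t_ms

#' @rdname sweep_trace
#' @export
n_sweeps <- function(x, channel = NULL) {
  cols <- names(x$samples)[-1]
  if (!is.null(channel)) cols <- grep(sprintf("^ch:%s:", channel), cols, value = TRUE)
  length(unique(sub("^ch:[^:]+:(sweep[0-9]+)$", "\\1", cols)))
}

#' Read and write sweep-set bundles
#'
#' A bundle is a plain-text pair: `<path>` (CSV, `t_ms` then
#' `ch:<name>:sweep<k>` columns, full round-trip numeric precision) and
#' `<path minus .csv>.meta.json` (units, protocol, metadata, optional ground
#' truth under `"truth"`). `write_sweepset()` then [read_sweepset()]
#' reproduces samples bit-exactly and metadata key-for-key.
#'
#' @param path Path to the bundle CSV; the sidecar path is derived by
#'   replacing `.csv` with `.meta.json`.
#' @return `read_sweepset()` returns a [sweep_set()]; `write_sweepset()`
#'   returns `path` invisibly.
#' @export
read_sweepset <- function(path) {
  if (!file.exists(path)) abort_validation(paste0("no such file: ", path))
  side <- sidecar_path(path)
  if (!file.exists(side)) abort_validation(paste0("missing metadata sidecar: ", side))
  samples <- read_numeric_csv(path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (k in c("sample_interval", "channels"))
    if (is.null(meta[[k]])) abort_validation(paste0("missing metadata key: ", k))
  protocol <- as.list(meta$protocol %||% list())
  sweep_set(samples,
            sample_interval = meta$sample_interval,
            channels = unlist(meta$channels),
            protocol = protocol,
            meta = as.list(meta$meta %||% list()))
}

#' @rdname read_sweepset
#' @param x A `sweep_set`.
#' @export
write_sweepset <- function(x, path) {
  validate_sweep_set(x)
  write_numeric_csv(x$samples, path)
  side <- list(sample_interval = x$sample_interval,
               channels = as.list(x$channels),
               protocol = x$protocol,
               meta = x$meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".meta.json")

# Lossless numeric CSV: doubles are written with %.17g (shortest form that
# always round-trips through a correctly rounded parser) and read back with
# base strtod. readr's fast float path is not correctly rounded in the last
# bit, which would break the bit-exact round-trip contract.
write_numeric_csv <- function(df, path) {
  cols <- lapply(df, function(col) {
    out <- sprintf("%.17g", col)
    short <- sprintf("%.15g", col)
    ok <- as.numeric(short) == col
    out[ok] <- short[ok]
    out
  })
  lines <- do.call(paste, c(cols, sep = ","))
  writeLines(c(paste(names(df), collapse = ","), lines), path)
  invisible(path)
}

read_numeric_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric", check.names = FALSE),
    error = function(e) abort_validation(paste0("parse error in ", path, ": ",
                                                conditionMessage(e))),
    warning = function(w) abort_validation(paste0("parse error in ", path, ": ",
                                                  conditionMessage(w))))
  tibble::as_tibble(df)
}

#' @export
autoplot.sweep_set <- function(object, channel = NULL, sweeps = NULL, ...) {
  long <- tidyr::pivot_longer(object$samples, -"t_ms",
                              names_to = c("channel", "sweep"),
                              names_pattern = "^ch:([^:]+):sweep([0-9]+)$",
                              values_to = "value")
  if (!is.null(channel)) long <- dplyr::filter(long, .data$channel %in% !!channel)
  if (!is.null(sweeps)) long <- dplyr::filter(long, .data$sweep %in% as.character(sweeps))
  ggplot2::ggplot(long, ggplot2::aes(.data$t_ms, .data$value, colour = .data$sweep)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}
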