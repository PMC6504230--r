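#' Analysis configuration
#'
#' Collects every cross-module tunable in one validated list. Defaults are
#' the package's documented conventions; unknown keys are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of class `calyxq_config`.
#'
#' @details Keys (units, default):
#' * `eq_fit_range` — 1-based stimulus indices for the EQ line (2:4).
#' * `eq_cumulative` — abscissa convention, `"exclusive"` (cumulative before
#'   stimulus n; makes |slope| = Pr exact in the pure-depletion model) or
#'   `"inclusive"`.
#' * `smn_steady_window` — number of final cumulative points fit (10).
#' * `mini_threshold_k` — detection threshold, multiples of robust noise SD (4).
#' * `mini_min_amp_pa` — minimum accepted mini amplitude, pA (10).
#' * `mini_refractory_ms` — events closer than this merge, ms (5).
#' * `mini_baseline_ms` — rolling-median baseline window, ms (20).
#' * `baseline_window_ms`, `baseline_gap_ms` — evoked baseline window length
#'   and its gap before the stimulus, ms (5, 0.5).
#' * `peak_window_ms` — evoked peak-search window after the stimulus, ms (5).
#' * `artifact_blank_ms` — post-stimulus blanking in peak search, ms (0.3).
#' * `cap_artifact_skip_ms` — capacitance artifact exclusion after each
#'   depolarization, ms (50).
#' * `cap_pre_window_ms`, `cap_post_window_ms` — single-pulse capacitance
#'   measurement windows, ms (50, 100); inside 10-Hz trains both shrink to 40.
#' * `abr_search_window_ms` — wave search window, ms (`c(0, 6)`).
#' * `abr_merge_window_ms` — peak dominance half-window, ms (0.2).
#' * `abr_threshold_k` — amplitude threshold criterion, multiples of noise SD (3).
#' * `abr_amplitude_mode` — `"peak_to_trough"` or `"baseline_to_peak"`.
#' * `welch` — use Welch rather than pooled t-tests (FALSE).
#' * `ptp_window_s` — post-tetanus averaging window, s (30).
#' @export
analysis_config <- function(...) {
  defaults <- list(
    eq_fit_range = 2:4,
    eq_cumulative = "exclusive",
    smn_steady_window = 10L,
    mini_threshold_k = 4,
    mini_min_amp_pa = 10,
    mini_refractory_ms = 5,
    mini_baseline_ms = 20,
    baseline_window_ms = 5,
    baseline_gap_ms = 0.5,
    peak_window_ms = 5,
    artifact_blank_ms = 0.3,
    cap_artifact_skip_ms = 50,
    cap_pre_window_ms = 50,
    cap_post_window_ms = 100,
    abr_search_window_ms = c(0, 6),
    abr_merge_window_ms = 0.2,
    abr_threshold_k = 3,
    abr_amplitude_mode = "peak_to_trough",
    welch = FALSE,
    ptp_window_s = 30
  )
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    abort_validation("all configuration overrides must be named")
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    abort_validation(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, over)
  if (!cfg$eq_cumulative %in% c("exclusive", "inclusive"))
    abort_validation("eq_cumulative must be 'exclusive' or 'inclusive'")
  if (!cfg$abr_amplitude_mode %in% c("peak_to_trough", "baseline_to_peak"))
    abort_validation("abr_amplitude_mode must be 'peak_to_trough' or 'baseline_to_peak'")
  structure(cfg, class = c("calyxq_config", "list"))
}
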