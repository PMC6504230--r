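#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an RRP estimate
#'
#' @param x An `rrp_estimate` from [eq_estimate()] or [smn_estimate()].
#' @param ... Unused.
#' @return `tidy()`: one row per quantity (`term`, `estimate`, `unit`);
#'   `glance()`: one row of fit diagnostics.
#' @export
tidy.rrp_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("rrp_amplitude", "pr", "replenish_rate", "slope", "intercept"),
    estimate = c(x$rrp_amplitude, x$pr, x$replenish_rate, x$slope, x$intercept),
    unit = c("nA", "", "nA/stimulus",
             if (x$method == "EQ") "" else "nA/stimulus", "nA"))
}

#' @rdname tidy.rrp_estimate
#' @export
glance.rrp_estimate <- function(x, ...) {
  tibble::tibble(method = x$method,
                 rrp_amplitude = x$rrp_amplitude,
                 pr = x$pr,
                 replenish_rate = x$replenish_rate,
                 cumulative_total = x$cumulative_total,
                 r_squared = x$r_squared,
                 n_fit_points = length(x$fit_points),
                 vesicle_count = if (is.null(x$vesicle_count)) NA_integer_
                                 else x$vesicle_count)
}

#' Tidy a post-tetanic potentiation result
#'
#' @param x A `ptp_result` from [ptp_analysis()].
#' @param ... Unused.
#' @return `tidy()`: the normalized post-tetanus time course;
#'   `glance()`: means, ratio and p-value in one row.
#' @export
tidy.ptp_result <- function(x, ...) x$post_timecourse

#' @rdname tidy.ptp_result
#' @export
glance.ptp_result <- function(x, ...) {
  tibble::tibble(pre_mean = x$pre_mean, pre_sem = x$pre_sem,
                 post_mean = x$post_mean, post_sem = x$post_sem,
                 ratio = x$ratio, p_value = x$p_value, paired = x$paired)
}

#' Tidy a capacitance-train result
#'
#' @param x A `cap_train_result` from [analyze_cap_train()].
#' @param ... Unused.
#' @return `tidy()`: the per-pulse table; `glance()`: train-level summary.
#' @export
tidy.cap_train_result <- function(x, ...) x$per_pulse

#' @rdname tidy.cap_train_result
#' @export
glance.cap_train_result <- function(x, ...) {
  tibble::tibble(n_pulses = nrow(x$per_pulse),
                 sigma_delta_cm_fF = x$sigma_delta_cm_fF,
                 resting_cm_pF = x$resting_cm_pF,
                 endo_tau_s = x$endo_tau_s)
}

#' Tidy an ABR wave set
#'
#' @param x An `abr_waveset` from [detect_waves()].
#' @param ... Unused.
#' @return `tidy()`: the per-wave tibble; `glance()`: detection summary.
#' @export
tidy.abr_waveset <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.abr_waveset
#' @export
glance.abr_waveset <- function(x, ...) {
  tibble::tibble(intensity = attr(x, "intensity"),
                 n_found = sum(x$found),
                 complete = attr(x, "complete"))
}
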