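#' Elmqvist-Quastel (EQ) estimate of the readily releasable pool
#'
#' Plots each train EPSC amplitude `A_n` against the cumulative amplitude
#' released before stimulus n, fits a line through the early depressing
#' points (default: the second through the fourth EPSC), and back-
#' extrapolates to the abscissa. The x-intercept estimates the pre-existing
#' pool (in EPSC-amplitude equivalents, nA) and the slope magnitude
#' estimates the release probability: in the pure-depletion model
#' `A_n = p (N0 q - cum_{n-1})`, so the points lie exactly on a line of
#' slope `-p` through `N0 q`. Under ongoing replenishment the EQ intercept
#' overestimates the pre-existing pool.
#'
#' @param train A [train_measurement()].
#' @param fit_range 1-based stimulus indices fit (default 2:4).
#' @param cumulative Abscissa convention: `"exclusive"` (cumulative before
#'   stimulus n; slope magnitude equals Pr exactly) or `"inclusive"`
#'   (cumulative through stimulus n; same x-intercept in the pure-depletion
#'   model, slope `-p/(1-p)`).
#' @param quantal_amp Optional mean mEPSC amplitude (pA) for a vesicle count.
#' @return An `rrp_estimate` object; see [tidy.rrp_estimate()].
#' @seealso [smn_estimate()], [vesicle_count()]
#' @export
eq_estimate <- function(train, fit_range = 2:4,
                        cumulative = c("exclusive", "inclusive"),
                        quantal_amp = NULL) {
  train <- as_train_measurement(train)
  cumulative <- match.arg(cumulative)
  a <- train$amplitude_nA
  if (length(a) < max(fit_range))
    abort_validation("train has fewer amplitudes than max(fit_range)")
  cum <- cumsum(a)
  x_all <- if (cumulative == "exclusive") c(0, cum[-length(cum)]) else cum
  x <- x_all[fit_range]; y <- a[fit_range]
  fit <- ls_line(x, y)
  if (fit$slope >= -1e-12)
    abort_validation("EQ inapplicable: non-negative slope (no depression over the fit range)")
  x_int <- -fit$intercept / fit$slope
  new_rrp_estimate(
    method = "EQ",
    rrp_amplitude = x_int,
    pr = abs(fit$slope),
    replenish_rate = NA_real_,
    cumulative_total = cum[length(cum)],
    slope = fit$slope, intercept = fit$intercept,
    r_squared = fit$r_squared, fit_points = fit_range,
    vesicle_count = if (!is.null(quantal_amp)) vesicle_count(x_int, quantal_amp),
    train = train,
    extra = list(cumulative = cumulative, x = x_all, y = a))
}

#' Schneggenburger-Meyer-Neher (SMN) estimate of the readily releasable pool
#'
#' Plots the cumulative EPSC amplitude against stimulus number, fits a line
#' through the steady-state points (default: the last 10 of the train), and
#' back-extrapolates to the ordinate. The y-intercept estimates the pool
#' decrement during stimulation (nA), the slope estimates the replenishment
#' rate (nA per stimulus), and `Pr = A_1 / RRP`. Because the intercept
#' measures the pool consumed rather than the pre-existing pool, SMN
#' underestimates the initial pool under ongoing replenishment (its
#' asymptotic intercept in the depletion-replenishment model is
#' `N0 q - r q / p`).
#'
#' @param train A [train_measurement()].
#' @param steady_window Number of final points fit (default 10).
#' @param quantal_amp Optional mean mEPSC amplitude (pA) for a vesicle count.
#' @return An `rrp_estimate` object.
#' @export
smn_estimate <- function(train, steady_window = 10, quantal_amp = NULL) {
  train <- as_train_measurement(train)
  a <- train$amplitude_nA
  n <- length(a)
  if (n < steady_window + 5)
    abort_validation("train too short: need length >= steady_window + 5")
  cum <- cumsum(a)
  idx <- (n - steady_window + 1):n
  fit <- ls_line(idx, cum[idx])
  if (fit$intercept <= 0)
    abort_validation("SMN inapplicable: non-positive y-intercept")
  new_rrp_estimate(
    method = "SMN",
    rrp_amplitude = fit$intercept,
    pr = a[1] / fit$intercept,
    replenish_rate = max(0, fit$slope),
    cumulative_total = cum[n],
    slope = fit$slope, intercept = fit$intercept,
    r_squared = fit$r_squared, fit_points = idx,
    vesicle_count = if (!is.null(quantal_amp)) vesicle_count(fit$intercept, quantal_amp),
    train = train,
    extra = list(cumulative_curve = cum))
}

new_rrp_estimate <- function(method, rrp_amplitude, pr, replenish_rate,
                             cumulative_total, slope, intercept, r_squared,
                             fit_points, vesicle_count = NULL, train = NULL,
                             extra = list()) {
  structure(list(method = method, rrp_amplitude = rrp_amplitude, pr = pr,
                 replenish_rate = replenish_rate,
                 cumulative_total = cumulative_total,
                 slope = slope, intercept = intercept, r_squared = r_squared,
                 fit_points = fit_points, vesicle_count = vesicle_count,
                 train = train, extra = extra),
            class = "rrp_estimate")
}

#' @export
print.rrp_estimate <- function(x, ...) {
  cat("<rrp_estimate> method: ", x$method, "\n", sep = "")
  cat(sprintf("  RRP = %.3g nA, Pr = %.3g", x$rrp_amplitude, x$pr))
  if (is.finite(x$replenish_rate))
    cat(sprintf(", replenishment = %.3g nA/stimulus", x$replenish_rate))
  cat("\n")
  cat(sprintf("  cumulative total = %.3g nA, R^2 = %.4f (points %s)\n",
              x$cumulative_total, x$r_squared,
              paste(range(x$fit_points), collapse = "-")))
  if (!is.null(x$vesicle_count))
    cat("  vesicle count = ", x$vesicle_count, "\n", sep = "")
  invisible(x)
}

#' Convert an RRP amplitude to a vesicle count
#'
#' Divides the pool estimate (nA) by the quantal size (the mean mEPSC
#' amplitude, pA). Rounds half away from zero.
#'
#' @param rrp_amplitude Pool estimate, nA (> 0).
#' @param quantal_amp Mean mEPSC amplitude, pA (> 0).
#' @return Integer vesicle count.
#' @examples
#' vesicle_count(33.4, 39.9)   # 837
#' vesicle_count(17.6, 33.4)   # 527
#' @export
vesicle_count <- function(rrp_amplitude, quantal_amp) {
  if (any(rrp_amplitude <= 0)) abort_validation("rrp_amplitude must be > 0 nA")
  if (any(quantal_amp <= 0)) abort_validation("quantal_amp must be > 0 pA")
  as.integer(round_half_away(rrp_amplitude * 1000 / quantal_amp))
}

#' Short-term depression profile of a train
#'
#' Normalizes each amplitude to the first response and summarises the
#' steady-state depression level as the mean of the last `steady_k`
#' normalized amplitudes.
#'
#' @param train A [train_measurement()].
#' @param steady_k Number of final stimuli averaged (default 10).
#' @return A tibble (`stimulus`, `time_ms`, `amplitude_nA`, `normalized`)
#'   with attribute `steady_state_ratio`; retrieve it with
#'   [steady_state_ratio()].
#' @export
depression_profile <- function(train, steady_k = 10) {
  train <- as_train_measurement(train)
  a <- train$amplitude_nA
  if (a[1] <= 0) abort_validation("first amplitude must be > 0 to normalize")
  d <- tibble::as_tibble(train)
  d$normalized <- a / a[1]
  ss <- mean(utils::tail(d$normalized, steady_k))
  structure(d, steady_state_ratio = ss, steady_k = steady_k,
            class = c("depression_profile", class(d)))
}

#' @rdname depression_profile
#' @param x A `depression_profile`.
#' @export
steady_state_ratio <- function(x) attr(x, "steady_state_ratio")

#' @export
autoplot.rrp_estimate <- function(object, ...) {
  tr <- object$train
  if (object$method == "EQ") {
    d <- tibble::tibble(x = object$extra$x, y = object$extra$y,
                        fitted = seq_along(object$extra$x) %in% object$fit_points)
    ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$fitted)) +
      ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                           colour = "red") +
      ggplot2::annotate("point", x = object$rrp_amplitude, y = 0, shape = 4,
                        size = 3, colour = "red") +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                   guide = "none") +
      ggplot2::labs(x = "cumulative eEPSC (nA)", y = "eEPSC amplitude (nA)",
                    title = sprintf("EQ: RRP = %.1f nA, Pr = %.2f",
                                    object$rrp_amplitude, object$pr)) +
      ggplot2::theme_minimal()
  } else {
    d <- tibble::tibble(n = seq_along(object$extra$cumulative_curve),
                        cum = object$extra$cumulative_curve,
                        fitted = seq_along(object$extra$cumulative_curve) %in% object$fit_points)
    ggplot2::ggplot(d, ggplot2::aes(.data$n, .data$cum)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$fitted)) +
      ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                           colour = "red") +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                   guide = "none") +
      ggplot2::labs(x = "stimulus number", y = "cumulative eEPSC (nA)",
                    title = sprintf("SMN: RRP = %.1f nA, Pr = %.2f, repl = %.2f nA/stim",
                                    object$rrp_amplitude, object$pr,
                                    object$replenish_rate)) +
      ggplot2::theme_minimal()
  }
}
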