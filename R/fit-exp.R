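# single-exponential decay fitting, shared by mini/evoked/capacitance analyses

# Fit y(t) = a * exp(-(t - t[1]) / tau) (+ optional floor c0) by least
# squares. Start values come from a log-linear fit on the positive samples;
# Levenberg-Marquardt then minimises the untransformed residuals so noisy
# samples near zero do not dominate. Returns list(tau, a, c0, ok).
fit_exp_decay <- function(t, y, with_offset = FALSE) {
  stopifnot(length(t) == length(y))
  ok_in <- is.finite(t) & is.finite(y)
  t <- t[ok_in]; y <- y[ok_in]
  if (length(t) < 3) return(list(tau = NA_real_, a = NA_real_, c0 = 0, ok = FALSE))
  ts <- t - t[1]
  y_floor <- if (with_offset) min(y) else 0
  pos <- (y - y_floor) > max(abs(y)) * 1e-6
  if (sum(pos) < 3) return(list(tau = NA_real_, a = NA_real_, c0 = 0, ok = FALSE))
  ll <- stats::lm.fit(cbind(1, ts[pos]), log(y[pos] - y_floor))
  slope <- unname(ll$coefficients[2])
  if (!is.finite(slope) || slope >= 0)
    return(list(tau = NA_real_, a = NA_real_, c0 = 0, ok = FALSE))
  tau0 <- -1 / slope
  a0 <- exp(unname(ll$coefficients[1]))
  fit <- if (with_offset) {
    try(minpack.lm::nlsLM(y ~ c0 + a * exp(-ts / tau),
                          start = list(a = a0, tau = tau0, c0 = y_floor),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        silent = TRUE)
  } else {
    try(minpack.lm::nlsLM(y ~ a * exp(-ts / tau),
                          start = list(a = a0, tau = tau0),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    # log-linear estimate still usable when the refinement fails
    return(list(tau = tau0, a = a0, c0 = y_floor, ok = TRUE))
  }
  cf <- stats::coef(fit)
  if (!is.finite(cf[["tau"]]) || cf[["tau"]] <= 0)
    return(list(tau = NA_real_, a = NA_real_, c0 = 0, ok = FALSE))
  list(tau = unname(cf[["tau"]]), a = unname(cf[["a"]]),
       c0 = if (with_offset) unname(cf[["c0"]]) else 0, ok = TRUE)
}
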