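# Independent closed-form oracles for the depletion-replenishment model.
# These never call the package's recursion: amplitudes come from the
# explicit geometric solution and line fits from the textbook OLS formulas.

# A_n = p q [ (n0 - r/p) (1-p)^(n-1) + r/p ] / 1000  (nA)
analytic_train_amplitudes <- function(n0, q, p, r, n) {
  k <- seq_len(n)
  p * q * ((n0 - r / p) * (1 - p)^(k - 1) + r / p) / 1000
}

ols_coef <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# EQ oracle: line through (cumulative before n, A_n), n in fit_range
oracle_eq <- function(n0, q, p, r, n = 50, fit_range = 2:4) {
  a <- analytic_train_amplitudes(n0, q, p, r, n)
  cum_before <- c(0, cumsum(a)[-n])
  cf <- ols_coef(cum_before[fit_range], a[fit_range])
  list(x_intercept = -cf[["intercept"]] / cf[["slope"]], slope = cf[["slope"]])
}

# SMN oracle: line through (n, cumulative through n) over the last `steady`
oracle_smn <- function(n0, q, p, r, n = 50, steady = 10) {
  a <- analytic_train_amplitudes(n0, q, p, r, n)
  idx <- (n - steady + 1):n
  cf <- ols_coef(idx, cumsum(a)[idx])
  list(y_intercept = cf[["intercept"]], slope = cf[["slope"]])
}

# analytic biexponential, unit peak, for signal-analysis fixtures
biexp_event <- function(t, rise, decay) {
  t_star <- log(decay / rise) * decay * rise / (decay - rise)
  s_peak <- exp(-t_star / decay) - exp(-t_star / rise)
  ifelse(t < 0, 0, (exp(-t / decay) - exp(-t / rise)) / s_peak)
}

# wrap a bare trace vector as a single-channel current sweep_set
as_current_sweep <- function(y, si, protocol = list(), meta = list()) {
  sweep_set(tibble::tibble(t_ms = (seq_along(y) - 1) * si, `ch:im:sweep1` = y),
            sample_interval = si, channels = c(im = "pA"),
            protocol = protocol, meta = meta)
}
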