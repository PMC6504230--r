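# internal helpers shared across modules

#' Derive a reproducible sub-seed for a pipeline component
#'
#' Simulators that draw from several independent random sources expand one
#' user-facing seed into per-component sub-seeds with a fixed counter scheme,
#' so that re-running a single component of a pipeline reproduces exactly the
#' draws it saw inside the full pipeline. The scheme is
#' `sub_seed = (seed + 1000003 * counter) mod (2^31 - 1)`: counters are fixed
#' small integers assigned per component (documented in each simulator).
#'
#' @param seed Integer master seed.
#' @param counter Non-negative integer component counter.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.numeric(counter), length(counter) == 1, counter >= 0)
  as.integer((as.numeric(seed) + 1000003 * as.numeric(counter)) %% 2147483647)
}

# truncated-normal draws, lower bound 0 (inverse-CDF method, exact)
rtnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

# least-squares line y = a + b x, returned with r.squared; no NA handling
ls_line <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  fit <- stats::lm.fit(cbind(1, x), y)
  a <- unname(fit$coefficients[1]); b <- unname(fit$coefficients[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  list(intercept = a, slope = b, r_squared = r2)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_validation <- function(msg) {
  rlang::abort(msg, class = "calyxq_validation_error")
}
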