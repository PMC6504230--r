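#' Simulate a depletion-replenishment eEPSC train
#'
#' Generates per-stimulus evoked amplitudes from the standard vesicle-pool
#' model underlying train-based RRP estimation: a pool of `n0` release-ready
#' vesicles, each released with probability `p` per stimulus, with `r`
#' vesicles restored per inter-stimulus interval. The expected amplitude of
#' stimulus n is `p * B_n * q` (pool `B_n` in vesicles, quantal size `q` in
#' pA); amplitudes are returned in nA.
#'
#' In `"expectation"` mode the deterministic recursion
#' `B_{n+1} = B_n - p B_n + r` is run with a real-valued pool (so `n0` and
#' `r` need not be integers). In `"binomial"` mode the released count is
#' drawn `Binomial(B_n, p)` and each released vesicle contributes a quantal
#' amplitude drawn from a normal with mean `q` and SD `q * q_cv`, truncated
#' at zero. The pool never drops below 0 and, unless `allow_overfill = TRUE`,
#' replenishment never raises it above `n0` (this keeps the zero-replenishment
#' pool-conservation law and pool potentiation modelling separate).
#'
#' @param n0 Initial pool size (vesicles, >= 1).
#' @param q Quantal amplitude, pA (mean miniature EPSC amplitude).
#' @param p Release probability per vesicle per stimulus, in (0, 1].
#' @param r Replenishment, vesicles per inter-stimulus interval (>= 0).
#' @param n_stimuli Number of stimuli (default 50).
#' @param freq Stimulation frequency, Hz (default 100).
#' @param mode `"expectation"` or `"binomial"`.
#' @param q_cv Quantal coefficient of variation (binomial mode; default 0.3).
#' @param allow_overfill Permit replenishment above `n0` (default FALSE).
#' @param seed Integer seed (binomial mode; required for reproducibility).
#' @return A [train_measurement()]; ground-truth parameters are echoed in
#'   `attr(, "meta")$truth`.
#' @examples
#' tr <- simulate_train(n0 = 800, q = 40, p = 0.35, r = 56)
#' head(tr)
#' @export
simulate_train <- function(n0, q, p, r, n_stimuli = 50, freq = 100,
                           mode = c("expectation", "binomial"),
                           q_cv = 0.3, allow_overfill = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(n0) || n0 < 1) abort_validation("n0 must be >= 1 vesicle")
  if (!is.numeric(q) || q <= 0) abort_validation("q must be > 0 pA")
  if (!is.numeric(p) || p <= 0 || p > 1) abort_validation("p must be in (0, 1]")
  if (!is.numeric(r) || r < 0) abort_validation("r must be >= 0")
  if (!is.numeric(n_stimuli) || n_stimuli < 1) abort_validation("n_stimuli must be >= 1")
  if (!is.numeric(freq) || freq <= 0) abort_validation("freq must be > 0 Hz")
  if (!is.numeric(q_cv) || q_cv < 0) abort_validation("q_cv must be >= 0")

  n_stimuli <- as.integer(n_stimuli)
  amps_pa <- numeric(n_stimuli)

  if (mode == "expectation") {
    b <- n0
    for (n in seq_len(n_stimuli)) {
      released <- p * b
      amps_pa[n] <- released * q
      b <- b - released + r
      if (!allow_overfill) b <- min(b, n0)
      b <- max(b, 0)
    }
  } else {
    if (!is.null(seed)) set.seed(derive_seed(seed, 1L))
    b <- round(n0)
    for (n in seq_len(n_stimuli)) {
      k <- stats::rbinom(1, b, p)
      amps_pa[n] <- if (k > 0) sum(rtnorm0(k, q, q * q_cv)) else 0
      b <- b - k + r
      if (!allow_overfill) b <- min(b, round(n0))
      b <- max(round(b), 0)
    }
  }

  train_measurement(
    amps_pa / 1000, freq = freq,
    meta = list(truth = list(n0 = n0, q_pA = q, p = p, r = r,
                             mode = mode, q_cv = q_cv,
                             allow_overfill = allow_overfill,
                             rrp_nA = n0 * q / 1000,
                             seed = seed)))
}
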