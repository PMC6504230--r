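---
title: "Quantal analysis of calyx of Held transmission: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal analysis of calyx of Held transmission: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calyxq)
```

# The scientific problem

At a chemical synapse, the response to a presynaptic action potential is set
by three presynaptic quantities: the readily releasable pool (RRP) of
primed vesicles, the probability $P_r$ that a pooled vesicle is released by
one stimulus, and the rate at which the pool is refilled between stimuli.
The calyx of Held, a giant axosomatic terminal in the auditory brainstem,
is the standard preparation for separating these quantities, because both
the terminal and its postsynaptic MNTB principal neuron can be
voltage-clamped directly. calyxq implements the complete desk-side analysis
chain of such experiments: train-based RRP estimation, miniature and evoked
EPSC quantification, capacitance-based exocytosis measurement, ABR waveform
analysis, and the group statistics used to compare genotypes — together
with simulators that generate every input class from models with known
ground truth.

# The depletion–replenishment model

All train analyses rest on one model. A pool of $B_n$ vesicles faces
stimulus $n$; a fraction $p$ is released, each vesicle contributing a
quantal amplitude $q$ (the mean miniature EPSC amplitude, in pA); $r$
vesicles are restored during each inter-stimulus interval:

$$ A_n = p\, B_n\, q, \qquad B_{n+1} = B_n - p B_n + r . $$

The recursion solves to
$B_n = (N_0 - r/p)(1-p)^{\,n-1} + r/p$, so amplitudes decay geometrically
from $A_1 = p N_0 q$ to the steady state $A_\infty = r q$, which is the
familiar depression profile of 100-Hz trains. `simulate_train()` runs this
recursion either deterministically (`mode = "expectation"`, real-valued
pool) or stochastically (`mode = "binomial"`: released counts are
$\mathrm{Binomial}(B_n, p)$ and quantal amplitudes are normal with CV
`q_cv`, truncated at zero — the truncation is our choice; no quantal
distribution is prescribed by the underlying experiments). Replenishment is
constant-rate: whether refilling accelerates with depletion
(calcium-dependent replenishment) is not specified by the experiments we
model, so the simplest assumption is implemented and noted here.
Replenishment never raises the pool above $N_0$ unless `allow_overfill =
TRUE`; the cap preserves the conservation law $\sum_n A_n \le N_0 q$ at
$r = 0$ and keeps pool potentiation (below) an explicit modelling step
rather than a side effect.

# The two RRP estimators

**EQ (Elmqvist–Quastel).** Each amplitude $A_n$ is plotted against the
cumulative amplitude released *before* stimulus $n$. In the pure-depletion
model $A_n = p\,(N_0 q - \mathrm{cum}_{n-1})$, so the points lie on a line
with slope $-p$ and abscissa intercept $N_0 q$: the x-intercept of a line
fit through the early points (default stimuli 2–4) estimates the
pre-existing pool, and $|slope|$ estimates $P_r$. The abscissa convention
matters: with the *exclusive* cumulative (our default) the slope is $-p$
exactly; with the inclusive cumulative the x-intercept is unchanged but the
slope becomes $-p/(1-p)$, which would break the identity $P_r = |slope|$.
Both are available (`cumulative = "exclusive" | "inclusive"`).

**SMN (Schneggenburger–Meyer–Neher).** The cumulative amplitude $C_n$ is
plotted against $n$; a line through the steady-state points (default: the
last 10 of 50) is back-extrapolated to the ordinate. The y-intercept
estimates the pool, the slope the replenishment rate (nA/stimulus), and
$P_r = A_1 / \mathrm{RRP}$.

**Biases are part of the method, not bugs.** With ongoing replenishment the
two estimators bracket the true pool. Asymptotically the SMN intercept is
$N_0 q - r q / p$ — it measures the pool *decrement* during stimulation,
not the pre-existing pool — while the EQ x-intercept exceeds $N_0 q$
because replenishment props up the early amplitudes. The package's tests
verify, over a grid of more than 100 parameter settings, that both
estimators agree with independently derived closed forms to a relative
error below $10^{-9}$ and that $\mathrm{EQ} \ge N_0 q \ge \mathrm{SMN}$
whenever $r > 0$. A practical corollary worth spelling out: at an operating
point with steady-state depression to 20% of the first response
($r = 0.2\,p N_0$), the SMN pool estimate is exactly 80% of the true pool
and the SMN $P_r$ is $p/0.8$. Estimates made with these estimators are
estimates of *their* respective pool constructs; recovering the generative
$N_0$ and $p$ to within a few percent from SMN output alone is not possible
in this regime, and the package makes no such claim. Correction variants
(replenishment-corrected SMN, deconvolution, variance–mean analysis) are
deliberately out of scope: the analysis chain mirrors the two plain
estimators used in the experiments it models.

`vesicle_count()` converts a pool amplitude to a vesicle number by dividing
by the quantal size; values are rounded half away from zero, so 33.4 nA /
39.9 pA gives 837 vesicles and 17.6 nA / 33.4 pA gives 527.

# Miniature and evoked EPSCs

`detect_minis()` uses threshold crossing on a baseline-subtracted trace:
the baseline is a 20-ms rolling median (robust to overlapping events), the
noise SD is $1.4826 \times \mathrm{MAD}$ of the baseline-subtracted trace,
and the default threshold is 4 SD with a 10-pA amplitude floor and a 5-ms
merge (refractory) window — conventional mini-detection practice; the
experiments we model report mini metrics but no algorithm. On the standard
synthetic fixture (40-pA events on 2-pA noise, SNR 20), recall and
precision both exceed 0.95 and the mean amplitude bias is under 5%.

Kinetics follow the field's conventions: the 10–90% rise time is
interpolated linearly between samples on the rising limb, and the decay
time constant is a least-squares single exponential. The decay fit runs
from **80% of the peak** down to 10% of the peak: immediately after the
peak of a biexponential event the fast rising component still contributes
(fitting literally from the peak of a 0.1/0.6-ms event returns 0.65 ms
rather than 0.6 ms), while by 80% of peak the event is effectively
mono-exponential and the fit recovers the true constant to about 1%. The
window is defined by peak fractions, not fixed durations, so fitted
constants are amplitude-independent. The reported decay time is a fitted
$\tau$, not a percent-decay time.

Evoked responses (`measure_epsc()`) are baseline-subtracted peak
magnitudes: a 5-ms baseline ending 0.5 ms before the stimulus, a 5-ms peak
window with the first 0.3 ms blanked (stimulus artifact). These windows are
our defaults, set by calyx EPSC latency and kinetics at these ages. For
paired pulses at 10-ms intervals, the second amplitude is measured from a
0.5-ms baseline immediately before pulse 2 — at $\tau \approx 1$ ms the
residual current of pulse 1 has decayed to well under 1%, so subtracting
the local baseline is as accurate as exponential extrapolation and much
simpler. `p4_leak_subtract()` implements the traditional p/4 protocol
(test sweep minus four times the mean of four quarter-amplitude sweeps);
anything linear in the stimulus cancels exactly.

Post-tetanic potentiation (`ptp_analysis()`) compares evoked amplitudes
before and after a 100-Hz, 3-s tetanus; the post-tetanus averaging window
defaults to 30 s (configurable — the averaging interval is not fixed by
the experiments we model). In the pool model a tetanus that enlarges the
pool by a factor $k$ scales amplitudes by exactly $k$ at fixed $p, q$,
which the tests verify.

# Capacitance-based exocytosis

Vesicle fusion adds membrane, so each depolarizing pulse steps the
terminal's capacitance up by $\Delta C_m$ (femtofarads), which then decays
with the endocytosis time constant. `measure_delta_cm()` is a difference
of window means with the first 50 ms after each pulse excluded
(conductance artifacts corrupt the capacitance estimate there — only this
exclusion is prescribed by the experiments; the window layout follows from
pulse geometry: pre 50 ms/post 100 ms for single pulses, both 40 ms inside
10-Hz trains, which exactly fills the 90-ms inter-pulse gap after the
skip). The endocytosis-induced bias of this measurement equals the window
average of $e^{-t/\tau}$; with $\tau \approx 20$ s and the default windows
it is below 0.5%, and the tests check the measurement against this
analytic integral, not against the nominal jump.

The 20-pulse train analysis (`analyze_cap_train()`) sums per-pulse jumps
into $\Sigma\Delta C_m$, the capacitance equivalent of the releasable pool,
and normalizes the cumulative time course to the first jump.
`fit_endocytosis()` fits a single exponential (with floor) to the
post-train decay; the "endocytosis rate" is reported as this time constant
in seconds. Calcium influx is quantified as the magnitude of the
trapezoidal integral of the baseline-subtracted current over the pulse
(`integrate_ca_charge()`), normalized to the resting capacitance
(pC/pF). The simulator's calcium channel is an instantaneous
Boltzmann–driving-force model,
$I(V) = g_{max}\, m_\infty(V)\,(V - E_{rev})$ with
$m_\infty(V) = 1/(1+e^{-(V-V_{half})/k})$; activation kinetics are omitted
because the analyses use only charge and peak. The default family
($V_{half} = -24$ mV, $k = 6$ mV, $E_{rev} = 45$ mV, $g_{max} = 12.5$ nS)
puts the most-negative current of the standard $-80\ldots+60$ mV grid at
$-10$ mV with a peak near $-625$ pA, matching the published I–V shape of
these terminals.

# ABR analysis

The auditory brainstem response is an averaged far-field potential with
five waves in the 6 ms after a click. `detect_waves()` takes the five
largest local maxima in the 0–6 ms window, requiring each to dominate its
±0.2-ms neighbourhood (twin peaks closer than that merge). Wave amplitude
is peak-to-following-trough by default — the dominant convention;
baseline-to-peak is available — and latency is the peak time.

Threshold is defined operationally, since "lowest intensity with a
reproducible waveform" is a visual criterion in practice. Two
operationalizations are provided: (a) the largest wave exceeds $k = 3$
times the noise SD of the pre-response segment, and (b) the Pearson
correlation of two replicate half-averages exceeds 0.5. Both are evaluated
on a matched-filter-smoothed copy of the recording (Gaussian kernel,
SD 0.15 ms, matched to the wave width): without smoothing, the maximum
peak-to-trough excursion of averaged broadband noise across a 6-ms window
essentially always exceeds 3 SD, and no amplitude criterion can separate
noise from signal. For criterion (a) the comparison uses baseline-to-peak
height against the smoothed-noise SD, computed as the raw pre-response SD
scaled by the kernel's L2 norm — valid because averaged noise is white at
40-µs sampling, and far more stable than estimating the SD from the ~25
smoothed (hence correlated) pre-response samples. The threshold is the
lowest intensity passing the criterion with every higher tested intensity
also passing; an isolated sub-threshold false positive therefore cannot
lower the estimate unless the whole run down to it passes. On the
simulator's conditions (5-dB steps, SNR ≈ 5.6 at threshold), criterion (a)
is within one 5-dB step of truth in 100% of tested seeds and exact in
about 83%; criterion (b) was exact in all tested seeds.

# Group statistics and small formulas

`summarize_group()` reports mean ± s.e.m. with the $n-1$ SD.
`compare_groups()` wraps the two-tailed Student's t-test — pooled variance
by default, matching the era's convention; Welch via `welch = TRUE` — and
the Mann–Whitney U test. No multiple-testing correction is applied, since
none is applied in the analyses we mirror. Degenerate inputs (essentially
constant data) return $p = 1$ for equal means and $p = 0$ for a nonzero
constant difference rather than erroring. `relative_expression()`
implements the comparative Ct method,
$2^{-\Delta\Delta C_t} \times 100\%$, with the control group at exactly
100%. `classify_vesicles()` counts docked (≤ 10 nm) and clustered
(≤ 200 nm) vesicles; "within" is interpreted inclusively, and docked
vesicles count among the clustered.

# What the simulators do and do not emulate

The generators reproduce the *statistical structure* the analyses consume:
geometric train depression with a replenishment floor, binomial release
noise with quantal variability, Poisson mini timing with biexponential
event shapes on Gaussian noise, capacitance steps with exponential
endocytosis and pulse-locked Boltzmann calcium currents, and five Gaussian
ABR waves with linear amplitude growth above a hard threshold. They do not
emulate calcium-dependent facilitation or replenishment, vesicle
priming-state heterogeneity, postsynaptic receptor saturation or
desensitization, series-resistance and space-clamp errors, non-white or
line-frequency noise, or non-Gaussian ABR wave shapes. Passing tests
therefore demonstrate that the analysis chain is correct *given the model
class*; they do not certify performance on recordings whose deviations
from these assumptions are large. All generators are bit-reproducible: one
master seed expands into per-component sub-seeds via
`derive_seed(seed, counter)` (documented counters per simulator), so a
component re-run in isolation sees the same draws as inside a pipeline.

# Numerical choices

Line fits are ordinary least squares without weighting. The EQ estimator
declares itself inapplicable when the fitted slope is not below
$-10^{-12}$ (no depression); SMN requires a positive y-intercept.
Exponential fits start from a log-linear fit on the positive samples and
refine with Levenberg–Marquardt on the untransformed residuals, so noisy
samples near zero do not dominate; when the refinement fails the
log-linear estimate is kept and flagged. Vesicle counts round half away
from zero. Times are milliseconds, zero-based at sweep start, with
half-open windows $[t_0, t_1)$. Bundle CSVs are written with shortest
round-trip decimal representation and parsed with a correctly rounded
parser, so write-then-read reproduces samples bit-exactly. Amplitudes are
stored as magnitudes with polarity in metadata (inward currents are
reported as positive nA magnitudes, as the field prints them).

# Problem sizes in the test suite

The suite verifies stochastic claims at sizes chosen to give stable
statistics: 1000 seeds for binomial-vs-expectation train means, 200 seeds
for the Poisson dispersion of mini counts and for SMN recovery at the WT
operating point, 110–120 settings for the estimator oracle grids, 40–60
seeds for noisy exponential-fit recovery, and 10–12 seeds for ABR
threshold recovery. Fixture traces use 20-kHz sampling for mini kinetics
and coarser grids (0.2–5 ms) where only amplitudes or slow decays matter.

# Known limitations

* The estimators inherit their classical biases under replenishment (see
  above); no corrected variants are provided.
* Mini detection has no overlapping-event decomposition; coincident events
  within the refractory window merge.
* Capacitance analysis assumes traces already demodulated to a capacitance
  channel (as produced by acquisition software); no Lindau–Neher admittance
  computation from raw current, and no slow/bulk endocytosis decomposition.
* The ABR module estimates per-click-intensity thresholds only; no
  frequency-specific audiograms.
* Readers exist only for the package's plain-text bundle format, not for
  proprietary acquisition formats.
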