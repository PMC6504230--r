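Package: calyxq
Title: Quantal Analysis of Synaptic Transmission at the Calyx of Held
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for presynaptic quantal analysis of calyx of Held
    recordings. Implements the Elmqvist-Quastel and
    Schneggenburger-Meyer-Neher train estimators of the readily releasable
    pool, release probability and vesicle replenishment rate; detection and
    kinetic quantification of miniature EPSCs; evoked EPSC measurement with
    p/4 leak subtraction, paired-pulse ratio and post-tetanic potentiation;
    membrane-capacitance exocytosis analysis (capacitance jumps, calcium
    charge density, endocytosis time constant, I-V curves); auditory
    brainstem response wave detection and threshold estimation; and group
    summaries with the comparisons conventional in the field. A synthetic
    data module generates every input class from parametric models with
    known ground truth (binomial depletion-replenishment release trains,
    Poisson miniature-event traces, capacitance sweeps with exponential
    endocytosis, Boltzmann-activated calcium current families, five-wave
    ABR waveforms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
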