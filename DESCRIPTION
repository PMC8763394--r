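Package: respsych
Title: Respiration-Resolved Psychophysics and Oscillatory Power Statistics
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links respiration phase, parieto-occipital band power and
    near-threshold detection performance. Provides a synthetic cohort
    generator (quasi-periodic respiration, a QUEST-driven observer whose
    detection threshold is sinusoidally modulated by respiration phase, and
    oscillatory band power phase-coupled to breathing over a 1/f background),
    respiration phase extraction with a 60-bin moving-window phase grid,
    Gaussian-copula mutual-information model comparison, phase-resolved
    Bayesian psychometric refitting, Morlet and multitaper spectral machinery
    with a surrogate-normalized modulation index and phase-triggered averages,
    harmonic linear mixed-effects models with permutation nulls,
    likelihood-ratio model comparison, cluster-based permutation tests, a
    circular lag scan and a bootstrap peak-lag confidence interval.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
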