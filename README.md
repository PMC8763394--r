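# respsych

Respiration-resolved psychophysics and oscillatory-power statistics.

Breathing modulates cortical excitability, and excitability modulates the
detection of weak visual stimuli. `respsych` implements the full analysis
chain linking **respiration phase**, **parieto-occipital band power**
(alpha, 8–13 Hz, an inverse excitability proxy) and **near-threshold
detection performance**, for researchers in computational neuroscience and
psychophysiology:

* **Respiration phase** — alternating peak/trough detection, piecewise-linear
  phase (trough → peak maps −π → 0, so inspiration is (−π, 0)), a Welch-style
  breathing spectrum (0–2 Hz in exactly 0.025 Hz steps), and the shared
  60-bin moving-window phase grid (step π/30, window ±π/10).
* **Behavior** — hit/miss classification
  (HR = n<sub>hits</sub>/(n<sub>hits</sub>+n<sub>misses</sub>); wrong-side
  reports excluded), and a Gaussian-copula mutual-information model
  comparison: does adding sin φ, cos φ of respiration phase to stimulus
  contrast carry extra information about detection? (Wilcoxon signed-rank
  group test on per-participant, bias-corrected MI gains.)
* **Psychometrics** — Bayesian grid fit of the 3AFC cumulative-Gaussian
  psychometric function p(c) = 1/3 + (2/3 − λ)·Φ((c − T)/w), and an
  iterative per-phase-bin refit of the threshold only (width and lapse
  fixed, Gaussian prior from the overall fit), yielding each participant's
  60-bin threshold course.
* **Spectral** — analytic Morlet transform (one-sided Gaussian filter),
  smoothed amplitude envelopes, DPSS multitaper TFRs, phase-triggered
  averages around peak inspiration, phase-binned power courses, and the
  entropy-based modulation index (20 phase bins) normalized against 200
  circular-shift surrogates.
* **Statistics** — harmonic linear mixed models
  T<sub>j</sub> = β₀ + (S<sub>1j</sub>+β₁)·sin φ + (S<sub>2j</sub>+β₂)·cos φ
  [+ power terms and interactions], ML-fitted with diagonal random slopes;
  the respiratory phase vector norm v = √(β₁²+β₂²) with a
  shuffled-course permutation null; likelihood-ratio model comparison;
  instantaneous power–threshold correlation with cluster correction; generic
  cluster-based permutation tests (1-D circular, 2-D/3-D grids); a circular
  lag scan locating the phase lag of the maximal power effect; and a
  bootstrap peak-lag confidence interval.
* **Synthetic cohorts** — quasi-periodic non-sinusoidal respiration
  (0.26 Hz, lognormal cycle jitter), a QUEST-staircase-driven observer whose
  threshold is sinusoidally modulated by respiration phase *and* driven by
  lagged band-envelope fluctuations (the excitability pathway), and
  phase-coupled band power over a 1/f background — with every generative
  parameter recorded for parameter-recovery testing.

## Worked example

Simulate a small cohort (8 participants, 2 runs of 720 trials) with a
phase modulation peaking at +78° (worst detection), alpha power coupled at
a −30° lag, and run the full pipeline:

```r
library(respsych)

cfg <- analysis_config(
  simulate = cohort_config(
    n_participants = 8, n_runs = 2, trials_per_run = 720, fs = 25, seed = 11,
    observer = observer_params(width = 0.12, threshold_mod_amp = 0.08),
    coupling = list(coupling_params("alpha", 10, mod_depth = 0.1,
                                    lag_deg = -30, behav_gain = 0.2,
                                    env_noise_sd = 0.5, env_noise_tau = 3))),
  n_perm_vector = 1000, n_perm_corr = 1000, n_perm_cluster = 1000,
  n_null_per_lag = 0, n_boot = 50, lag_engine = "lmem", seed = 11)

bundle <- run_full_analysis(cfg)
print(bundle)
#> <results_bundle>
#>   mean hit rate: 0.620
#>   MI gain: mean delta 0.0157 bits, Wilcoxon z = 2.45, p = 0.00781
#>   vector norm: v = 1.1673, p = 0.000999
#>   alpha LMEM: t(474) = -0.24, LRT chi2(3) = 39.05
#>   peak lag: -36 deg, bootstrap CI [-210.0, 82.6] deg
```

Reading the output: the staircase held performance near its 60 % target
(mean hit rate 0.620). Adding respiration phase to contrast increased the
mutual information with detection by 0.0157 bits on average (signed-rank
p = 0.008) — respiration phase carries information about detection beyond
the staircase-driven contrast. The harmonic mixed model's sine/cosine
weights combine to a vector norm of 1.17 that exceeded every one of 1000
within-participant course shuffles (p ≈ 0.001): the threshold course is
phase-locked to breathing. The lag scan places the maximal alpha-power
effect at −36°, one bin from the generative −30° (alpha leads behavior);
at this small cohort size the single-cohort alpha t statistic is weak and
the bootstrap CI is wide — peak-lag precision needs paper-scale cohorts
(30 participants × 6 runs), as the methods vignette discusses.

Individual stages are exported too, e.g.:

```r
tr <- gen_respiration(respiration_params(), duration = 300, fs = 300, seed = 1)
ph <- interpolate_phase(tr, detect_extrema(tr))
breathing_spectrum(tr)$dominant_freq   # ~0.26 Hz
mi <- modulation_index(envelope, ph)   # phase-amplitude coupling per row
```

A command-line driver is installed at
`system.file("cli", "respsych", package = "respsych")` with subcommands
`simulate`, `phase`, `refit`, `full` (YAML or JSON configs; exit codes
0 ok / 2 validation failure / 3 stage failure).

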