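---
title: "Linking respiration phase, alpha power and detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking respiration phase, alpha power and detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Spontaneous breathing is a slow physiological rhythm that modulates cortical
excitability, and cortical excitability in turn modulates the detectability
of weak visual stimuli. `respsych` implements a complete, tested analysis
chain for quantifying this three-way relationship from (a) a continuous
respiration trace, (b) a table of near-threshold detection trials run under
an adaptive staircase, and (c) band-limited oscillatory power (the
parieto-occipital alpha band, 8–13 Hz, serving as an inverse excitability
proxy). Because the package is developed and validated without access to a
real MEG cohort, it ships a first-class synthetic-data generator whose
ground truth is known exactly, so every stage of the chain can be tested as
a parameter-recovery problem.

# Respiration phase

Respiration phase is defined piecewise-linearly: each trough (maximal
expiration) is mapped to ±π and each peak (maximal inspiration) to 0, with
linear interpolation in between. Inspiration therefore occupies phases
(−π, 0), expiration (0, π). Phase is a *cycle-normalized* time, not the
Hilbert phase of a band-passed signal: it is exact for the asymmetric,
non-sinusoidal cycles of real breathing.

`detect_extrema()` finds alternating peaks and troughs using persistence
pruning (adjacent peak/trough pairs whose amplitude difference falls below
`prominence`, default 0.5 z-units, are deleted smallest-first) followed by a
minimum same-type distance (peak-to-peak at least `min_cycle / 2`, default
half of one 0.26 Hz cycle). Samples before the first and after the last
extremum have undefined phase and are excluded from binning rather than
extrapolated.

All downstream stages share one phase grid (`phase_bin_grid()`): 60 centers
stepping by π/30 from −π, each with a moving membership window of ±π/10.
Windows overlap (a generic angle falls into 6 bins, 7 exactly at a center)
and wrap circularly across ±π. Membership at the exact window boundary is
inclusive — a deterministic tie rule.

The breathing spectrum uses 20 s segments with 50 % overlap, linear
detrending, a single Hann taper, and zero-padding to 40 s, which fixes the
frequency increment at exactly 0.025 Hz regardless of sampling rate.

# The observer and the staircase

The simulated observer detects a Gabor of contrast $c$ with probability

$$ p(c) = \gamma + (1 - \gamma - \lambda)\,
   \Phi\!\left(\frac{c - T(\varphi, t)}{w}\right), \qquad \gamma = 1/3 $$

with lapse $\lambda$ (default 0.02), width $w$ (default 0.15 contrast
units), and a momentary threshold

$$ T(\varphi, t) = T_0 + A\cos(\varphi - \varphi_T) +
   \sum_b \kappa_b\, \tilde a_b(t; \ell_b) $$

combining a sinusoidal respiration-phase modulation (amplitude $A$, worst
phase $\varphi_T$, defaults 0.05 and +78°, i.e. best detection around
−102°, mid-inspiration) with an *excitability pathway*: $\tilde a_b$ is the
z-scored band envelope read out at a phase-domain lag $\ell_b$ (negative =
power leads behavior), scaled by `behav_gain` $\kappa_b$ (defaults 0.10 for
alpha at −30°, 0.04 for beta at −10°).

The excitability pathway is essential, not decorative: a power course that
is a pure harmonic of respiration phase is *exactly collinear* with the
sine/cosine regressors of the mixed model, so a group-level power effect
and a lag scan are unidentifiable in principle without shared
power–behavior fluctuations. The pathway reads the envelope at an exact
phase offset via the unwrapped generative phase; an earlier fixed-time-shift
implementation biased recovered lags toward zero because cycle durations
vary.

Target contrast is placed by a QUEST staircase: a grid posterior over
log10 threshold, Weibull likelihood with $\gamma = 1/3$ (slope 3.5, lapse
0.02), placement and estimate at the posterior mean, aiming at 60 % hits.
The staircase is self-correcting: at its stationary point the observer's
hit rate at the placement intensity equals the target regardless of the
Weibull/cumulative-Gaussian mismatch. Catch trials (1/3 of the 720 trials
per run) never update the posterior. Simulated sessions settle at a
post-burn-in hit rate of ≈ 0.60 (the acceptance report recomputes this).

# What the generator emulates — and what it does not

Cycle durations are lognormal with CV 0.08/0.26 around a 0.26 Hz mean
(Gaussian jitter produces implausibly fast cycles that no peak detector can
honor); inspiration takes 45 % of the cycle by default. Amplitude noise is
band-limited (0.5 s moving average) like belt drift — white noise at the
sampling rate would make detected extrema wander across the flat cosine
tops. Band envelopes follow
$a_b(t) = A_0 (1 + m_b \cos(\varphi - \varphi_b)) + \eta_b(t)$ with slow
noise $\eta_b$ (timescale `env_noise_tau`, default 1 s; the cohort defaults
use the τ that makes bin-level fluctuations realistic). A shared
per-participant scaling couples behavioral modulation amplitude and power
modulation depth (`mod_amp_shared_rel`), producing the between-participant
covariance that group-level power–threshold analyses rely on.

Not emulated: multi-channel sensor geometry, eye movements and blinks,
cardiac artifacts, line noise, head motion, or non-stationary breathing
modes. A green recovery test therefore establishes that the *analysis
chain* is correct and calibrated on data with the stated statistical
structure — it does not certify robustness to every artifact of real
recordings.

# Psychometric refitting

`fit_psychf()` is a Bayesian grid fit (log-threshold × log-width × lapse,
101 × 101 × 11 points by default, flat priors over a data-driven span,
posterior means as point estimates). The grid spans are proportional to the
median contrast, making the fit exactly scale-equivariant. The refit
(`refit_threshold_by_phase()`) resolves an ambiguity in its sources: width
and lapse are *fixed* at the overall estimates, and only the threshold is
refit per bin, with a Gaussian prior centered on the overall threshold
whose SD is the overall posterior SD times `prior_scale` (default 2). Bins
with fewer than 15 trials are imputed by circular linear interpolation and
flagged; more than 20 % under-populated bins is an error. Each course is
z-scored (exactly mean 0, SD 1) before entering group statistics.

# Mutual information

The behavioral model comparison uses Gaussian-copula mutual information:
each continuous variable is rank-transformed to a standard-normal marginal,
and MI between detection (hit/miss) and the features is computed from
class-wise Gaussian entropies with the analytic psi-function small-sample
correction, in bits. GCMI is a lower bound; e.g. a near-copy of the labels
yields ≈ 0.73 bits, not 1. Because the 3-feature estimate (contrast, sin φ,
cos φ) carries a different bias than the 1-feature one, the per-participant
gain is permutation-bias-corrected (20 phase shuffles, seeded) — without
this the group signed-rank test rejected at ≈ 0.15 instead of 0.05 under
the null (measured over 200 replicates). The group test is a Wilcoxon
signed-rank: exact for n ≤ 25 without ties, otherwise the normal
approximation with continuity correction (the z statistic is always
reported from the approximation).

# Spectral machinery

The Morlet transform is implemented in the frequency domain as a Gaussian
bandpass with a Heaviside cutoff (negative frequencies exactly zero, so
coefficients are analytic), bandwidth scaled per center frequency with
`n_cycles` (default 6) and gain 2 at the center so a unit cosine has unit
envelope. Envelopes are magnitudes smoothed by a centered boxcar (300 ms
default) whose window shrinks at the edges (mean-preserving). Multitaper
TFRs use DPSS tapers computed from the Slepian tridiagonal eigenproblem
(validated against an independent implementation to machine precision),
500 ms windows stepped by 50 ms, 2 Hz spectral smoothing below 30 Hz and
5 Hz above.

The modulation index bins envelope amplitude into 20 equal phase bins over
(−π, π] (left-open, right-closed, one bin centered on peak inspiration),
normalizes the bin means to a distribution, and reports
$(\log N - H)/\log N$ — 0 for a uniform distribution, 1 for a single-bin
point mass; natural logs cancel in the ratio. Significance is normalized
against 200 circular time shifts of the phase series (minimum shift 1 s to
avoid near-identity surrogates): `(raw − mean)/sd` in surrogate SD units.

# Group statistics

Threshold courses are modelled as

$$ T_{j}(\omega) = \beta_0 + (S_{1j}+\beta_1)\sin\omega +
   (S_{2j}+\beta_2)\cos\omega + \dots + e_j $$

optionally adding z-scored alpha (and beta) power courses and their
sine/cosine (and alpha × beta) interactions, each with a per-participant
random slope. Random-effects covariance is diagonal (30 participants cannot
support a full 10 × 10 covariance), fitting is by maximum likelihood so
likelihood-ratio comparisons between nested models are valid, t statistics
use the residual convention df = n − p (1794 for the alpha model on a
30 × 60 design, 1790 with beta), and model comparison df counts fixed
effects only (3 and 4 for the two steps).

The respiration effect is summarized as the vector norm
$v = \sqrt{\beta_1^2 + \beta_2^2}$ with preferred phase
$\operatorname{atan2}(\beta_1, \beta_2)$, tested against a null built by
independently shuffling each participant's course across bins and
refitting (add-one permutation p). Because the sine/cosine design is
balanced and identical across participants, the ML fixed effects equal the
mean of per-participant OLS coefficients *exactly* (asserted in tests to
1e−10), so the 5000 permutation refits use the closed form rather than
5000 mixed-model fits.

The lag scan circularly shifts each participant's power course against
their threshold course in π/30 steps, refits the alpha model at each lag,
and takes the lag of the maximal alpha t value (ties toward smaller |lag|);
cluster adjacency on the phase axis is circular. Two engines exist: the
mixed model per lag (default, spec-faithful) and a fast per-participant OLS
pooled by DerSimonian–Laird inverse-variance weighting, used inside the
500-iteration participant bootstrap where 30 000 mixed-model fits are
infeasible. Plain unweighted pooling is unstable when a power course is
nearly collinear with the harmonics; the inverse-variance weights emulate
the mixed model's shrinkage. The bootstrap CI is a circular percentile
interval centered on the circular mean of peak lags.

Cluster-based permutation tests threshold element-wise dependent-samples t
maps at p = 0.05 (two-tailed for condition contrasts, one-tailed positive
for the MI and instantaneous-correlation tests), sum the statistic within
contiguous clusters (runs on a line or circle, rectilinear connectivity on
2-D/3-D grids), and compare against the max-cluster distribution over
random sign flips of whole participant maps. The instantaneous-correlation
test correlates power and threshold across participants per bin and builds
its null by shuffling the participant order of one matrix. Under pure-noise
simulation the any-cluster rate was 0.052 ± 0.007 (1000 replicates).

# Numerical choices and degenerate inputs

* z-scoring a constant vector returns zeros with a `degenerate` flag
  (phase-triggered average rows, flat power courses).
* Bin-membership boundary ties are inclusive; MI phase bins are left-open
  right-closed; both are deterministic conventions.
* Permutation p values use the add-one rule `(1 + #null ≥ stat)/(n + 1)`.
* Empty moving-window bins are circularly interpolated and flagged, never
  silently filled.
* All randomness flows from one master seed through named substreams
  (`derive_seed`), so every result is bit-reproducible; identical
  configurations produce byte-identical result files.

# Known limitations

* The per-bin refit assumes the width and lapse of the overall fit hold at
  every phase; a phase-dependent width would bias thresholds.
* GCMI lower-bounds MI; absolute bit values should not be compared across
  estimators.
* The fast lag-scan engine approximates the mixed model; peak-lag estimates
  from the bootstrap inherit that approximation.
* At small cohort sizes and trial counts the single-cohort peak-lag
  estimate wobbles by one to two bins (the acceptance suite validates
  blind lag recovery at course level, where it is exact); small cohorts
  should rely on the bootstrap CI rather than the point estimate.
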