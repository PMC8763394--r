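# Parameter objects for the synthetic cohort generator.
#
# Defaults encode the stated experimental world: breathing at 0.26 Hz
# (cycle-duration CV 0.08/0.26), a 3AFC observer with guess rate 1/3 run by a
# QUEST staircase at 60% hit rate over 6 runs x 720 trials (1/3 catch), and
# band power whose amplitude is coupled to respiration phase.

#' Respiration generator parameters
#'
#' @param mean_rate mean breathing frequency in Hz.
#' @param rate_cv coefficient of variation of cycle durations (unitless).
#' @param inspiration_fraction fraction of each cycle spent trough-to-peak.
#' @param amp_noise_sd additive amplitude noise SD in z-units.
#' @return an object of class `respiration_params`.
#' @export
respiration_params <- function(mean_rate = 0.26, rate_cv = 0.08 / 0.26,
                               inspiration_fraction = 0.45,
                               amp_noise_sd = 0.1) {
  stopifnot(mean_rate > 0, rate_cv >= 0,
            inspiration_fraction > 0, inspiration_fraction < 1,
            amp_noise_sd >= 0)
  structure(list(mean_rate = mean_rate, rate_cv = rate_cv,
                 inspiration_fraction = inspiration_fraction,
                 amp_noise_sd = amp_noise_sd),
            class = "respiration_params")
}

#' Simulated observer parameters
#'
#' Detection follows a 3AFC cumulative-Gaussian psychometric function
#' `p(c) = guess + (1 - guess - lapse) * Phi((c - T(phase)) / width)` with a
#' phase-dependent threshold
#' `T(phase) = threshold_base + threshold_mod_amp * cos(phase - threshold_mod_phase)`.
#'
#' @param threshold_base baseline detection threshold (contrast units).
#' @param threshold_mod_amp amplitude of the sinusoidal threshold modulation.
#' @param threshold_mod_phase respiration phase (radians) of maximal threshold
#'   (i.e. worst sensitivity).
#' @param width psychometric width (Gaussian SD, contrast units).
#' @param lapse lapse rate in \[0, 0.1\].
#' @param guess guess rate, fixed at 1/3 for the 3AFC design.
#' @param false_alarm_rate probability of reporting a side on catch trials.
#' @param wrong_side_rate probability that a detected target is reported on
#'   the wrong side.
#' @return an object of class `observer_params`.
#' @export
observer_params <- function(threshold_base = 0.72, threshold_mod_amp = 0.05,
                            threshold_mod_phase = deg2rad(78),
                            width = 0.15, lapse = 0.02, guess = 1 / 3,
                            false_alarm_rate = 0, wrong_side_rate = 0) {
  stopifnot(width > 0, lapse >= 0, lapse <= 0.1,
            isTRUE(all.equal(guess, 1 / 3)),
            threshold_mod_amp >= 0,
            threshold_base - threshold_mod_amp > 0,
            false_alarm_rate >= 0, false_alarm_rate <= 1,
            wrong_side_rate >= 0, wrong_side_rate <= 1)
  structure(list(threshold_base = threshold_base,
                 threshold_mod_amp = threshold_mod_amp,
                 threshold_mod_phase = wrap_angle(threshold_mod_phase),
                 width = width, lapse = lapse, guess = guess,
                 false_alarm_rate = false_alarm_rate,
                 wrong_side_rate = wrong_side_rate),
            class = "observer_params")
}

#' Phase-amplitude coupling parameters for one frequency band
#'
#' The band envelope is
#' `baseline_amp * (1 + mod_depth * cos(phase - coupling_phase))` plus noise.
#' If `lag_deg` is given, the effective coupling phase is derived per
#' participant as `threshold_mod_phase + lag_deg * pi/180`, so that the power
#' modulation leads (negative lag) or trails (positive lag) the behavioral
#' threshold modulation by a known angle.
#'
#' @param band band label, e.g. "alpha".
#' @param center_freq oscillation center frequency in Hz.
#' @param mod_depth fractional amplitude modulation m in \[0, 1).
#' @param coupling_phase radians of envelope maximum relative to respiration
#'   phase (ignored when `lag_deg` is non-NULL).
#' @param lag_deg phase offset in degrees of the power modulation relative to
#'   the threshold modulation; `NULL` to use `coupling_phase` directly.
#' @param noise_exponent slope of the 1/f background.
#' @param baseline_amp baseline envelope amplitude (arbitrary units).
#' @param env_noise_sd additive envelope noise SD (fraction of baseline).
#' @param env_noise_tau timescale (seconds) of the band-limited envelope
#'   noise; slow fluctuations emulate waxing/waning of oscillatory power.
#' @param behav_gain contrast units of observer threshold change per z-unit
#'   of (lagged) envelope fluctuation: the excitability pathway through
#'   which band power drives behavior beyond the common harmonic.
#' @return an object of class `coupling_params`.
#' @export
coupling_params <- function(band = "alpha", center_freq = 10, mod_depth = 0.2,
                            coupling_phase = 0, lag_deg = -30,
                            noise_exponent = 1, baseline_amp = 1,
                            env_noise_sd = 0.2, env_noise_tau = 1,
                            behav_gain = 0) {
  stopifnot(center_freq > 0, mod_depth >= 0, mod_depth < 1,
            baseline_amp > 0, env_noise_sd >= 0, env_noise_tau >= 0)
  structure(list(band = band, center_freq = center_freq,
                 mod_depth = mod_depth,
                 coupling_phase = wrap_angle(coupling_phase),
                 lag_deg = lag_deg, noise_exponent = noise_exponent,
                 baseline_amp = baseline_amp, env_noise_sd = env_noise_sd,
                 env_noise_tau = env_noise_tau, behav_gain = behav_gain),
            class = "coupling_params")
}

#' Cohort simulation configuration
#'
#' @param n_participants number of simulated participants.
#' @param n_runs experimental runs per participant.
#' @param trials_per_run trials per run (divisible by 3 when
#'   `catch_fraction = 1/3`).
#' @param catch_fraction fraction of catch (target-absent) trials.
#' @param fs sampling rate of the respiration trace in Hz.
#' @param seed master seed; fully determines all randomness.
#' @param observer an [observer_params()] object (cohort mean).
#' @param respiration a [respiration_params()] object.
#' @param coupling list of [coupling_params()], one per band.
#' @param jitter list of between-participant jitter settings:
#'   `threshold_base_rel` (relative SD), `coupling_phase_sd_deg`,
#'   `mod_phase_sd_deg`, and `mod_amp_shared_rel` (relative SD of a shared
#'   scaling applied to both the threshold modulation amplitude and the
#'   power modulation depth, creating the between-participant covariance
#'   that the group-level power-threshold analyses rely on).
#' @param iti mean inter-trial interval in seconds.
#' @param target_hr staircase target hit rate.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 30, n_runs = 6,
                          trials_per_run = 720, catch_fraction = 1 / 3,
                          fs = 300, seed = 1,
                          observer = observer_params(),
                          respiration = respiration_params(),
                          coupling = list(
                            coupling_params("alpha", 10, lag_deg = -30,
                                            behav_gain = 0.10),
                            coupling_params("beta", 22, mod_depth = 0.1,
                                            lag_deg = -10,
                                            behav_gain = 0.04)),
                          jitter = list(threshold_base_rel = 0.10,
                                        coupling_phase_sd_deg = 10,
                                        mod_phase_sd_deg = 10,
                                        mod_amp_shared_rel = 0.3),
                          iti = 0.63, target_hr = 0.60) {
  stopifnot(n_participants >= 1, n_runs >= 1, trials_per_run >= 3,
            catch_fraction >= 0, catch_fraction < 1, fs > 0)
  if (isTRUE(all.equal(catch_fraction, 1 / 3)) && trials_per_run %% 3 != 0) {
    stop("trials_per_run must be divisible by 3 when catch_fraction = 1/3")
  }
  stopifnot(inherits(observer, "observer_params"),
            inherits(respiration, "respiration_params"))
  if (inherits(coupling, "coupling_params")) coupling <- list(coupling)
  stopifnot(all(vapply(coupling, inherits, TRUE, "coupling_params")))
  structure(list(n_participants = n_participants, n_runs = n_runs,
                 trials_per_run = trials_per_run,
                 catch_fraction = catch_fraction, fs = fs,
                 seed = as.integer(seed), observer = observer,
                 respiration = respiration, coupling = coupling,
                 jitter = jitter, iti = iti, target_hr = target_hr),
            class = "cohort_config")
}
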