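# Shared fixtures, all built in code at test time.

# Direct behavioral simulation (no staircase): trials at jittered contrasts
# around the observer's threshold, detection from the generative psychometric
# function. Cheap input for MI / refit tests that do not exercise QUEST.
sim_trials_direct <- function(n = 480, obs = observer_params(), seed = 1,
                              contrast_sd = 0.1) {
  withr::with_seed(seed, {
    phase <- runif(n, -pi, pi)
    contrast <- pmax(0.05, rnorm(n, obs$threshold_base, contrast_sd))
    p <- observer_detection_prob(contrast, phase, obs)
    data.frame(contrast = contrast, phase = phase,
               detected = runif(n) < p)
  })
}

# Harmonic course matrix with per-participant phase jitter + noise; the
# noise is circularly smoothed over +-3 bins, mirroring the moving-window
# (+-pi/10) correlation structure of real refit courses
sim_courses <- function(P = 30, amp = 0.6, phi = deg2rad_t(78),
                        phase_sd = deg2rad_t(10), noise = 0.8, seed = 1,
                        grid = phase_bin_grid()) {
  withr::with_seed(seed, {
    t(sapply(seq_len(P), function(j) {
      pj <- phi + rnorm(1, 0, phase_sd)
      e <- rnorm(grid$n)
      sm <- sapply(seq_len(grid$n), function(i) {
        mean(e[((i - 1 + (-3:3)) %% grid$n) + 1])
      })
      sm <- sm / sd(sm) * noise
      as.numeric(scale(amp * cos(grid$centers - pj) + sm))
    }))
  })
}

deg2rad_t <- function(d) d * pi / 180
rad2deg_t <- function(r) r * 180 / pi

circ_err_deg <- function(a, b) {
  ((a - b + 180) %% 360) - 180
}

# memoized medium synthetic cohort with analyzed threshold/power courses,
# shared by the recovery tests (built once per test run); a strongly but
# plausibly coupled world so recovery assertions are informative at test
# scale (12 participants x 2 runs, 30 Hz)
.cohort_cache <- new.env(parent = emptyenv())
recovery_cohort <- function(seed = 42, P = 12, runs = 2) {
  key <- sprintf("c_%d_%d_%d", seed, P, runs)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cfg <- cohort_config(
    n_participants = P, n_runs = runs, trials_per_run = 720, fs = 30,
    seed = seed,
    observer = observer_params(width = 0.12, threshold_mod_amp = 0.08),
    coupling = list(coupling_params("alpha", 10, mod_depth = 0.1,
                                    lag_deg = -30, behav_gain = 0.2,
                                    env_noise_sd = 0.5, env_noise_tau = 3)),
    jitter = list(threshold_base_rel = 0.1, coupling_phase_sd_deg = 6,
                  mod_phase_sd_deg = 8, mod_amp_shared_rel = 0.2))
  coh <- gen_cohort(cfg)
  courses <- lapply(coh$participants, function(p) {
    out <- classify_trials(p$trials, 20)
    d <- out[out$outcome != "excluded", ]
    fit <- fit_psychf(d$contrast, d$outcome == "hit",
                      grid_n = 41, lapse_n = 5)
    refit_threshold_by_phase(d$contrast, d$outcome == "hit", d$phase, fit,
                             grid_n = 41)
  })
  res <- list(cohort = coh,
              courses = courses,
              thresh = course_matrix(courses),
              alpha = t(sapply(coh$participants,
                               function(p) p$power_courses[, "alpha"])))
  .cohort_cache[[key]] <- res
  res
}

# course-level cohort with a known phase lag between power and threshold:
# shared harmonic (per-participant phase jitter) plus a shared smooth
# residual, the alpha course leading by lag_deg; bin-level emulation of the
# structure the trial-level pipeline produces
sim_lagged_courses <- function(lag_deg, P = 20, seed = 1, amp = 0.5,
                               res_sd = 0.6, noise = 0.5,
                               grid = phase_bin_grid()) {
  withr::with_seed(seed, {
    w <- grid$centers
    kb <- round(lag_deg / rad2deg_t(grid$step))
    th <- al <- matrix(0, P, grid$n)
    for (j in seq_len(P)) {
      phi <- deg2rad_t(78) + rnorm(1, 0, deg2rad_t(8))
      res <- as.numeric(stats::filter(rnorm(grid$n + 20), rep(1, 9) / 9))
      res <- res[10:(9 + grid$n)]
      res <- res / sd(res) * res_sd
      th[j, ] <- scale(amp * cos(w - phi) + res +
                         rnorm(grid$n, 0, noise))
      al[j, ] <- scale(amp * cos(w - phi - deg2rad_t(lag_deg)) +
                         res[((seq_len(grid$n) - 1 - kb) %% grid$n) + 1] +
                         rnorm(grid$n, 0, noise))
    }
    list(th = th, al = al)
  })
}
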