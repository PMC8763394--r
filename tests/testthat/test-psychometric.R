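# Psychometric fitting and the phase-resolved threshold refit.

test_that("overall fit recovers generative parameters", {
  obs <- observer_params(threshold_mod_amp = 0)
  errs <- sapply(1:20, function(s) {
    d <- sim_trials_direct(480, obs, seed = 300 + s, contrast_sd = 0.12)
    fit <- fit_psychf(d$contrast, d$detected, grid_n = 61, lapse_n = 7)
    c(t = fit$threshold / obs$threshold_base - 1,
      w = fit$width / obs$width - 1)
  })
  expect_lt(median(abs(errs["t", ])), 0.10)
  expect_lt(median(abs(errs["w", ])), 0.25)
})

test_that("fitted function honors the fixed guess rate and scale equivariance", {
  d <- sim_trials_direct(480, observer_params(threshold_mod_amp = 0),
                         seed = 2)
  fit <- fit_psychf(d$contrast, d$detected)
  expect_equal(psychf_prob(0, fit), 1 / 3, tolerance = 1e-4)
  fit2 <- fit_psychf(2 * d$contrast, d$detected)
  expect_equal(fit2$threshold, 2 * fit$threshold, tolerance = 1e-9)
  expect_equal(fit2$width, 2 * fit$width, tolerance = 1e-9)
  expect_error(fit_psychf(d$contrast[1:10], d$detected[1:10]), "20 trials")
  expect_error(fit_psychf(d$contrast, rep(TRUE, 480)), "unidentifiable")
})

test_that("refit with a dominant prior returns the overall threshold everywhere", {
  d <- sim_trials_direct(600, observer_params(), seed = 5)
  fit <- fit_psychf(d$contrast, d$detected, grid_n = 61, lapse_n = 7)
  tc <- refit_threshold_by_phase(d$contrast, d$detected, d$phase, fit,
                                 prior_scale = 1e-6, grid_n = 61)
  expect_equal(length(tc$threshold), 60)
  expect_lt(max(abs(tc$threshold - fit$threshold)) / fit$threshold, 1e-3)
})

test_that("refit z-scoring is exact and lowered thresholds are tracked", {
  obs <- observer_params(threshold_mod_amp = 0.15 * 0.72,
                         threshold_mod_phase = deg2rad_t(78))
  grid <- phase_bin_grid()
  courses <- sapply(1:4, function(s) {
    d <- sim_trials_direct(2500, obs, seed = 6 + s, contrast_sd = 0.12)
    fit <- fit_psychf(d$contrast, d$detected, grid_n = 61, lapse_n = 7)
    tc <- refit_threshold_by_phase(d$contrast, d$detected, d$phase, fit,
                                   grid_n = 61)
    expect_equal(mean(tc$threshold_z), 0, tolerance = 1e-12)
    expect_equal(sd(tc$threshold_z), 1, tolerance = 1e-12)
    tc$threshold_z
  })
  # argmax of the mean recovered course near the generative peak phase,
  # argmin near the opposite phase (+-2 bins)
  m <- rowMeans(courses)
  expect_lte(circ_dist(grid$centers[which.max(m)], deg2rad_t(78)),
             2 * grid$step + 1e-9)
  expect_lte(circ_dist(grid$centers[which.min(m)], deg2rad_t(78 - 180)),
             2 * grid$step + 1e-9)
})

test_that("null refits rarely exceed |z| > 3", {
  # true clean rate must be >= 0.95; with 40 replicates the 1% binomial
  # quantile under p = 0.95 is 35, so fewer than 35 clean runs rejects
  n_clean <- 0
  for (s in 1:40) {
    d <- sim_trials_direct(1200, observer_params(threshold_mod_amp = 0),
                           seed = 900 + s, contrast_sd = 0.12)
    fit <- fit_psychf(d$contrast, d$detected, grid_n = 41, lapse_n = 5)
    tc <- refit_threshold_by_phase(d$contrast, d$detected, d$phase, fit,
                                   grid_n = 41)
    if (all(abs(tc$threshold_z) <= 3)) n_clean <- n_clean + 1
  }
  expect_gte(n_clean, qbinom(0.01, 40, 0.95))
})

test_that("under-populated bins are imputed or rejected", {
  d <- sim_trials_direct(400, observer_params(), seed = 7)
  fit <- fit_psychf(d$contrast, d$detected, grid_n = 41, lapse_n = 5)
  # squeeze all phases into a quarter cycle: most bins under-populated
  expect_error(refit_threshold_by_phase(d$contrast, d$detected,
                                        d$phase / 8, fit, grid_n = 41),
               "under-populated")
})

test_that("grand average behaves on degenerate and recovery inputs", {
  grid <- phase_bin_grid()
  z <- as.numeric(scale(cos(grid$centers - 1)))
  mk <- function(v) structure(list(threshold = v, threshold_z = v,
                                   n_trials = rep(100, 60), imputed = rep(FALSE, 60),
                                   grid = grid), class = "threshold_course")
  ga <- grand_average_course(list(mk(z), mk(z)))
  expect_equal(ga$mean, z)
  expect_equal(ga$sem, rep(0, 60))
  ga2 <- grand_average_course(list(mk(z), mk(-z)))
  expect_equal(ga2$mean, rep(0, 60))
  expect_error(grand_average_course(list(mk(z))), "2 participants")
  # cohort-level extremum recovery from simulated courses: median argmax
  # error over 5 independent cohorts within +-2 bins of the true phase
  errs <- sapply(1:5, function(s) {
    m <- sim_courses(P = 30, amp = 1.2, phase_sd = deg2rad_t(6),
                     noise = 0.35, seed = 9 + s)
    ga3 <- grand_average_course(m)
    circ_dist(grid$centers[which.max(ga3$mean)], deg2rad_t(78))
  })
  expect_lte(median(errs), 2 * grid$step + 1e-9)
})
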