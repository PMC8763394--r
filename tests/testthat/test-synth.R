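# Synthetic generator: respiration, observer, staircase, coupled power,
# cohort bundle.

test_that("noiseless periodic respiration has exact peak-to-peak interval", {
  p <- respiration_params(mean_rate = 0.25, rate_cv = 0,
                          inspiration_fraction = 0.5, amp_noise_sd = 0)
  tr <- gen_respiration(p, duration = 40, fs = 100, seed = 1)
  ex <- attr(tr, "true_extrema")
  expect_true(all(diff(ex$peak) == 100 / 0.25))
  # detected extrema agree with ground truth
  det <- detect_extrema(tr, min_cycle = 2)
  expect_true(all(abs(sort(det$peak) - sort(ex$peak[ex$peak > 1])) <= 1))
})

test_that("default respiration yields the expected number of cycles", {
  tr <- gen_respiration(respiration_params(), duration = 300, fs = 300,
                        seed = 2)
  ex <- detect_extrema(tr)
  expect_lte(abs(length(ex$peak) - 0.26 * 300), 4)
})

test_that("respiration generation is deterministic and validates duration", {
  p <- respiration_params()
  a <- gen_respiration(p, 60, 50, seed = 7)
  b <- gen_respiration(p, 60, 50, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_error(gen_respiration(p, 3, 50, seed = 1), "duration")
})

test_that("observer psychometric function has the stated asymptotes", {
  obs <- observer_params()
  expect_equal(observer_detection_prob(1e6, 0, obs), 1 - obs$lapse)
  expect_equal(observer_detection_prob(0, 0, obs), 1 / 3,
               tolerance = 1e-4)
  expect_error(simulate_observer_trials(-0.1, 0, "left", obs), "negative")
})

test_that("hit rate is phase-dependent with the configured modulation", {
  obs <- observer_params(threshold_mod_amp = 0.1,
                         threshold_mod_phase = -pi / 2)
  phases <- seq(-pi, pi - pi / 8, by = pi / 8)
  hr <- vapply(seq_along(phases), function(i) {
    r <- simulate_observer_trials(rep(obs$threshold_base, 2e4), phases[i],
                                  "left", obs, seed = 100 + i)
    mean(r == "left")
  }, 0)
  # detection worst where the threshold peaks, best at the opposite phase
  expect_equal(phases[which.min(hr)], -pi / 2, tolerance = 1e-9)
  expect_lt(abs(circ_err_deg(rad2deg_t(phases[which.max(hr)]), 90)), 45 + 1e-9)
})

test_that("QUEST converges to the target-performance contrast", {
  obs <- observer_params(threshold_mod_amp = 0)
  c60 <- obs$threshold_base +
    obs$width * qnorm((0.6 - obs$guess) / (1 - obs$guess - obs$lapse))
  last100 <- vapply(1:5, function(s) {
    tt <- run_quest_session(obs, rep(0, 480), seed = s)
    mean(tail(tt$contrast, 100))
  }, 0)
  expect_lt(abs(mean(last100) - c60) / c60, 0.10)
})

test_that("QUEST hit rate settles near 60% and validates target range", {
  obs <- observer_params()
  hr <- vapply(1:20, function(s) {
    tt <- run_quest_session(obs, runif(480, -pi, pi), seed = 1000 + s)
    mean(tt$detected[-(1:20)])
  }, 0)
  expect_lt(abs(mean(hr) - 0.60), 0.05)
  expect_error(run_quest_session(obs, rep(0, 10), target_hr = 0.2), "range")
})

test_that("a near-step observer drives the staircase to the step location", {
  obs <- observer_params(width = 1e-4, threshold_mod_amp = 0, lapse = 0.01)
  tt <- run_quest_session(obs, rep(0, 300), seed = 3)
  expect_lt(abs(mean(tail(tt$contrast, 50)) - obs$threshold_base) /
              obs$threshold_base, 0.05)
})

test_that("coupled power envelope obeys the stated modulation law", {
  ph <- seq(-pi, pi, length.out = 2001)
  cp0 <- coupling_params(mod_depth = 0, env_noise_sd = 0)
  e0 <- gen_coupled_power(ph, cp0, fs = 100, seed = 1)$envelope
  expect_equal(max(e0) - min(e0), 0, tolerance = 1e-12)
  cp <- coupling_params(mod_depth = 0.5, coupling_phase = 0,
                        env_noise_sd = 0)
  e <- gen_coupled_power(ph, cp, fs = 100, seed = 1)$envelope
  expect_equal(ph[which.max(e)], 0, tolerance = 2 * pi / 2000)
  expect_equal(max(e) / min(e), 3, tolerance = 1e-9)
  expect_true(all(e > 0))
  expect_error(gen_coupled_power(ph, cp, 100, mod_depth = 1), "mod_depth")
})

test_that("phase-binned envelope recovers the coupling phase", {
  tr <- gen_respiration(respiration_params(amp_noise_sd = 0), 300, 100,
                        seed = 5)
  ph <- attr(tr, "true_phase")
  cp <- coupling_params(mod_depth = 0.3, coupling_phase = pi / 3,
                        env_noise_sd = 0.1)
  env <- gen_coupled_power(ph, cp, 100, seed = 6)$envelope
  grid <- phase_bin_grid()
  bins <- phase_binning(ph, grid)
  course <- vapply(bins, function(i) mean(env[i]), 0)
  err <- circ_dist(grid$centers[which.max(course)], pi / 3)
  expect_lte(err, grid$step + 1e-9)
})

test_that("one simulated run has the stated trial mix and cohort is deterministic", {
  cfg <- cohort_config(n_participants = 2, n_runs = 1, trials_per_run = 720,
                       fs = 30, seed = 9)
  coh <- gen_cohort(cfg)
  t1 <- coh$participants[[1]]$trials
  expect_equal(nrow(t1), 720)
  expect_equal(sum(t1$side == "left"), 240)
  expect_equal(sum(t1$side == "right"), 240)
  expect_equal(sum(t1$side == "none"), 240)
  coh2 <- gen_cohort(cfg)
  expect_identical(serialize(coh$participants, NULL),
                   serialize(coh2$participants, NULL))
  expect_identical(coh$ground_truth, coh2$ground_truth)
})
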