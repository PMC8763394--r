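# Spectral machinery: Morlet transform, envelopes, multitaper TFR, PTA,
# phase-binned power, modulation index.

test_that("Morlet transform is analytic with flat envelope on a pure tone", {
  fs <- 200
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  sig <- cos(2 * pi * 10 * t)
  co <- morlet_transform(sig, fs, c(5, 10, 20))
  n <- length(t)
  interior <- round(0.05 * n):round(0.95 * n)
  env <- Mod(co[2, interior])
  expect_lt(sd(env) / mean(env), 0.01)
  expect_equal(mean(env), 1, tolerance = 0.01)
  # Heaviside: no negative-frequency content in any coefficient row
  sp <- stats::fft(co[2, ])
  neg <- sp[(n %/% 2 + 2):n]
  expect_lt(max(Mod(neg)) / max(Mod(sp)), 1e-10)
  expect_error(morlet_transform(sig, fs, 150), "Nyquist")
})

test_that("Morlet envelope tracks an amplitude-modulated tone", {
  fs <- 200
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  true_env <- 1 + 0.5 * cos(2 * pi * 0.26 * t)
  sig <- true_env * cos(2 * pi * 10 * t)
  co <- morlet_transform(sig, fs, 10)
  env <- amplitude_envelope(co, fs, smooth = 0.3)[1, ]
  interior <- round(0.05 * length(t)):round(0.95 * length(t))
  expect_gt(cor(env[interior], true_env[interior]), 0.99)
})

test_that("amplitude envelope smoothing is mean-preserving with edge shrink", {
  m <- matrix(complex(real = rep(2, 100)), 1)
  expect_equal(amplitude_envelope(m, 10, smooth = 0)[1, ], rep(2, 100))
  expect_equal(amplitude_envelope(m, 10, smooth = 1)[1, ], rep(2, 100))
  # boxcar of a unit impulse has mass 1
  imp <- matrix(complex(real = c(rep(0, 50), 1, rep(0, 49))), 1)
  sm <- amplitude_envelope(imp, 10, smooth = 1)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
})

test_that("DPSS tapers are orthonormal and concentrated", {
  tap <- dpss_tapers(128, nw = 2.5, k = 4)
  expect_equal(crossprod(tap), diag(4), tolerance = 1e-8)
  # leading taper concentrates energy in band |f| <= W (both spectrum sides)
  s <- Mod(stats::fft(c(tap[, 1], numeric(384))))^2
  inband <- (sum(s[1:11]) + sum(s[503:512])) / sum(s) # W = 2.5/128 ~ 10/512
  expect_gt(inband, 0.99)
})

test_that("multitaper TFR is flat on white noise and quadratic in amplitude", {
  withr::with_seed(21, {
    fs <- 200
    n_ep <- 1000
    ep <- matrix(rnorm(n_ep * 240), n_ep)
    tf <- multitaper_tfr(ep, fs, t_start = -1, time_range = c(-0.75, -0.35),
                         freqs = seq(6, 39, by = 3))
    pm <- apply(tf$power, 3, mean)
    expect_lt((max(pm) - min(pm)) / mean(pm), 0.10)
    tf2 <- multitaper_tfr(ep[1:50, ] / 2, fs, t_start = -1,
                          time_range = c(-0.75, -0.35),
                          freqs = seq(6, 39, by = 3))
    tf <- list(power = tf$power[1:50, , , , drop = FALSE])
    expect_equal(tf2$power, tf$power / 4, tolerance = 1e-12)
    expect_error(multitaper_tfr(ep[, 1:50, drop = FALSE], fs, win = 0.5),
                 "window")
  })
})

test_that("tone burst localizes in time and frequency", {
  fs <- 200
  tt <- seq(-1.25, 0.75 - 1 / fs, by = 1 / fs)
  sig <- ifelse(tt < 0, cos(2 * pi * 10 * tt), 0)
  ep <- matrix(rep(sig, 10), nrow = 10, byrow = TRUE)
  tf <- multitaper_tfr(ep, fs, t_start = -1.25, time_range = c(-1, 0.4),
                       freqs = 5:20)
  pre <- tf$times < -0.3
  post <- tf$times > 0.3
  f10 <- which(tf$freqs == 10)
  p_pre <- mean(tf$power[, , f10, pre])
  p_post <- mean(tf$power[, , f10, post])
  expect_gt(p_pre / p_post, 50)
  pf <- apply(tf$power[, , , pre, drop = FALSE], 3, mean)
  expect_equal(tf$freqs[which.max(pf)], 10)
})

test_that("match_and_contrast subsamples deterministically and is unbiased", {
  withr::with_seed(5, {
    hits <- matrix(rnorm(60 * 40), 60)
    miss <- matrix(rnorm(25 * 40), 25)
    d1 <- match_and_contrast(hits, miss, seed = 3)
    d2 <- match_and_contrast(hits, miss, seed = 3)
    expect_identical(d1, d2)
    # equal counts: deterministic difference without subsampling
    d3 <- match_and_contrast(miss, miss, seed = 99)
    expect_equal(d3, rep(0, 40))
    expect_error(match_and_contrast(hits, miss[0, , drop = FALSE]), "miss")
    # null: difference near zero at large trial counts
    h2 <- matrix(rnorm(500 * 20), 500)
    m2 <- matrix(rnorm(400 * 20), 400)
    dd <- match_and_contrast(h2, m2, seed = 4)
    expect_lt(mean(abs(dd)) / (1 / sqrt(400)), 2.5)
  })
})

test_that("phase-triggered average peaks at peak inspiration and z-scores rows", {
  p <- respiration_params(rate_cv = 0, inspiration_fraction = 0.5,
                          amp_noise_sd = 0)
  tr <- gen_respiration(p, 120, 50, seed = 1)
  ph <- interpolate_phase(tr, detect_extrema(tr))
  env <- 1 + 0.5 * cos(ifelse(is.na(ph$phase), 0, ph$phase))
  halfwin <- 40
  pta <- phase_triggered_average(rbind(env, env * 3), ph, halfwin)
  expect_equal(dim(pta), c(2, 2 * halfwin))
  expect_equal(rowMeans(pta), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(pta, 1, sd), c(1, 1), tolerance = 1e-12)
  expect_equal(which.max(pta[1, ]), halfwin + 1, tolerance = 2)
  # constant envelope: degenerate rows flagged, returned as zeros
  pta0 <- phase_triggered_average(matrix(1, 1, length(env)), ph, halfwin)
  expect_true(attr(pta0, "degenerate_rows")[1])
  expect_equal(pta0[1, ], rep(0, 2 * halfwin))
  expect_error(phase_triggered_average(matrix(env, 1), ph, 1e6), "peaks")
})

test_that("phase-binned power course recovers the coupling phase", {
  tr <- gen_respiration(respiration_params(amp_noise_sd = 0), 240, 50,
                        seed = 3)
  ph <- interpolate_phase(tr, detect_extrema(tr))
  grid <- phase_bin_grid()
  phi0 <- -pi / 3
  env <- 1 + 0.4 * cos(ifelse(is.na(ph$phase), 0, ph$phase) - phi0)
  course <- bin_power_by_phase(env, ph, grid)
  expect_length(course, 60)
  pk <- grid$centers[which.max(course)]
  expect_lte(circ_dist(pk, phi0), grid$step + 1e-9)
  # zero modulation: raw course flat before z-scoring
  c0 <- bin_power_by_phase(rep(2, length(env)), ph, grid)
  expect_lt(sd(attr(c0, "raw")), 1e-9)
  # band averaging over matrix rows
  em <- rbind(env, 10 * env, rep(1, length(env)))
  cb <- bin_power_by_phase(em, ph, grid, band = c(8, 13),
                           freqs = c(9, 11, 30))
  expect_equal(which.max(cb), which.max(course))
})

test_that("modulation index matches its entropy definition and the oracle", {
  tr <- gen_respiration(respiration_params(amp_noise_sd = 0.05), 200, 50,
                        seed = 4)
  ph <- interpolate_phase(tr, detect_extrema(tr))
  env <- 1 + 0.5 * cos(ifelse(is.na(ph$phase), 0, ph$phase))
  mi <- modulation_index(env, ph, n_surr = 50, seed = 9)
  # independent brute-force oracle: bin, normalize, entropy
  ok <- ph$valid
  k <- pmin(20, floor((ph$phase[ok] + pi) / (2 * pi / 20)) + 1)
  bm <- tapply(env[ok], k, mean)
  pr <- bm / sum(bm)
  oracle <- (log(20) + sum(pr * log(pr))) / log(20)
  expect_equal(mi$raw, oracle, tolerance = 1e-7)
  expect_gt(mi$normalized, 3)
  # uniform envelope -> raw 0; single-bin mass -> raw 1
  mi0 <- modulation_index(rep(2, length(env)), ph, n_surr = 10, seed = 1)
  expect_equal(mi0$raw, 0, tolerance = 1e-12)
  spike <- as.numeric(ph$phase > 0 & ph$phase <= pi / 10) # one full MI bin
  spike[is.na(ph$phase)] <- 0
  mi1 <- modulation_index(spike + 1e-12, ph, n_surr = 10, seed = 1)
  expect_gt(mi1$raw, 0.95)
  expect_error(modulation_index(rep(0, length(env)), ph), "all-zero")
})

test_that("raw MI is scale-invariant and monotone in modulation depth", {
  tr <- gen_respiration(respiration_params(amp_noise_sd = 0), 150, 50,
                        seed = 5)
  ph <- interpolate_phase(tr, detect_extrema(tr))
  base <- ifelse(is.na(ph$phase), 0, ph$phase)
  raws <- vapply(seq(0, 0.9, by = 0.1), function(m) {
    modulation_index((1 + m * cos(base)), ph, n_surr = 2, seed = 1)$raw
  }, 0)
  expect_true(all(diff(raws) >= -1e-12))
  mi_a <- modulation_index(1 + 0.3 * cos(base), ph, n_surr = 2, seed = 1)
  mi_b <- modulation_index(5 * (1 + 0.3 * cos(base)), ph, n_surr = 2,
                           seed = 1)
  expect_equal(mi_a$raw, mi_b$raw, tolerance = 1e-12)
})

test_that("normalized MI is ~standard-normal under the null", {
  withr::with_seed(6, {
    tr <- gen_respiration(respiration_params(), 120, 50, seed = 7)
    ph <- interpolate_phase(tr, detect_extrema(tr))
    z <- vapply(1:30, function(i) {
      env <- abs(1 + stats::filter(rnorm(length(ph$phase)), rep(1, 25) / 25,
                                   sides = 2))
      env[is.na(env)] <- 1
      modulation_index(as.numeric(env), ph, n_surr = 60,
                       seed = 100 + i)$normalized
    }, 0)
    expect_lt(abs(mean(z)), 0.5)
    expect_gt(sd(z), 0.6)
    expect_lt(sd(z), 1.7)
  })
})

test_that("MI group test flags a coupled frequency and stays calibrated", {
  withr::with_seed(8, {
    q95 <- qnorm(0.95)
    mk <- function(effect) {
      m <- matrix(rnorm(10 * 15, 0, 0.5), 10)
      if (effect) m[, 8] <- q95 + 1 + rnorm(10, 0, 0.2)
      m
    }
    gt <- mi_group_test(mk(TRUE), q95, n_perm = 500, seed = 2)
    sig_bins <- which(gt$sig_mask)
    expect_true(8 %in% sig_bins)
    # null calibration at reduced size
    rate <- mean(vapply(1:120, function(i) {
      g <- mi_group_test(mk(FALSE) + q95, q95, n_perm = 200,
                         seed = 500 + i)
      any(g$significant)
    }, TRUE))
    expect_lte(rate, 0.10)
  })
})
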