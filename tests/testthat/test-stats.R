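# Harmonic mixed models, vector-norm permutation test, likelihood-ratio
# comparison, instantaneous correlation, cluster permutation, lag scan,
# bootstrap peak lag.

grid60 <- phase_bin_grid()

# helper mirroring the internal circular shift used by lag_scan
shift_courses_test <- function(m, k) {
  nb <- ncol(m)
  idx <- ((seq_len(nb) - 1 + k) %% nb) + 1
  m[, idx, drop = FALSE]
}

test_that("pure harmonic courses are recovered and the fast path is exact", {
  w <- grid60$centers
  withr::with_seed(1, {
    th <- t(sapply(1:6, function(j) 2 + 3 * sin(w) + 4 * cos(w) +
                     rnorm(60, 0, 1e-6)))
  })
  m <- fit_harmonic_lmem(th, grid = grid60)
  expect_equal(unname(m$beta["sin_r"]), 3, tolerance = 1e-4)
  expect_equal(unname(m$beta["cos_r"]), 4, tolerance = 1e-4)
  expect_lt(m$sigma2, 1e-8)
  # closed-form OLS pooling equals the ML fixed effects exactly (balanced
  # identical design), also on noisy data
  th2 <- sim_courses(P = 12, seed = 3)
  m2 <- fit_harmonic_lmem(th2, grid = grid60)
  fb <- harmonic_fixed_betas(th2, grid = grid60)
  expect_equal(unname(fb$beta[c("sin_r", "cos_r")]),
               unname(m2$beta[c("sin_r", "cos_r")]), tolerance = 1e-10)
})

test_that("residual d.f. follow the n_obs - n_fixed convention", {
  th <- sim_courses(P = 30, seed = 4)
  al <- sim_courses(P = 30, phi = deg2rad_t(48), seed = 5)
  be <- sim_courses(P = 30, phi = deg2rad_t(68), seed = 6)
  m4 <- fit_harmonic_lmem(th, al, grid = grid60)
  expect_equal(m4$df, 1794)
  expect_equal(unname(m4$t), unname(m4$beta / m4$se))
  m5 <- fit_harmonic_lmem(th, list(alpha = al, beta = be), grid = grid60)
  expect_equal(m5$df, 1790)
  expect_error(fit_harmonic_lmem(th[1:2, ]), "3 participants")
})

test_that("vector norm and its phase behave as specified", {
  expect_equal(vector_norm(3, 4)$v, 5)
  expect_equal(vector_norm(0, 0)$v, 0)
  # rotation invariance: rotating the (sin, cos) coefficient pair preserves v
  withr::with_seed(2, {
    b <- rnorm(2)
    for (ang in runif(5, 0, 2 * pi)) {
      br <- c(cos(ang) * b[1] - sin(ang) * b[2],
              sin(ang) * b[1] + cos(ang) * b[2])
      expect_equal(vector_norm(br[1], br[2])$v, vector_norm(b[1], b[2])$v)
    }
  })
  # phase estimate matches the generative modulation phase within one bin
  th <- sim_courses(P = 30, amp = 0.8, noise = 0.5, seed = 7)
  m <- fit_harmonic_lmem(th, grid = grid60)
  ph <- vector_norm(m$beta["sin_r"], m$beta["cos_r"])$phase
  expect_lte(circ_dist(ph, deg2rad_t(78)), deg2rad_t(6) + 1e-9)
})

test_that("vector-norm permutation test detects strong modulation", {
  th <- sim_courses(P = 15, amp = 1, noise = 0.7, seed = 8)
  vt <- permutation_vector_norm_test(th, n_perm = 1000, seed = 9)
  expect_equal(vt$p, 1 / 1001) # empirical v exceeds every null
  expect_lte(circ_dist(vt$phase, deg2rad_t(78)), deg2rad_t(12))
  expect_error(permutation_vector_norm_test(th, n_perm = 10), "100")
})

test_that("null vector-norm distributions are exchangeable across batches", {
  th <- sim_courses(P = 10, amp = 0, noise = 1, seed = 10)
  a <- permutation_vector_norm_test(th, n_perm = 400, seed = 11)$null
  b <- permutation_vector_norm_test(th, n_perm = 400, seed = 12)$null
  expect_gt(suppressWarnings(ks.test(a, b)$p.value), 0.01)
})

test_that("likelihood-ratio comparison is valid for nested ML fits", {
  th <- sim_courses(P = 12, seed = 13)
  al <- sim_courses(P = 12, phi = deg2rad_t(48), seed = 14)
  m2 <- fit_harmonic_lmem(th, grid = grid60)
  m4 <- fit_harmonic_lmem(th, al, grid = grid60)
  lr <- lrt_compare(m2, m4)
  expect_equal(lr$df, 3)
  expect_gte(lr$chisq, 0)
  be <- sim_courses(P = 12, phi = deg2rad_t(68), seed = 15)
  m5 <- fit_harmonic_lmem(th, list(alpha = al, beta = be), grid = grid60)
  expect_equal(lrt_compare(m4, m5)$df, 4)
  # identical models: statistic 0, p = 1
  same <- lrt_compare(m2, fit_harmonic_lmem(th, grid = grid60))
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  expect_error(lrt_compare(m4, m2), "nested")
})

test_that("instantaneous correlation flags identical courses and validates input", {
  th <- sim_courses(P = 10, seed = 16)
  res <- instantaneous_correlation_test(th, th, n_perm = 500, seed = 17)
  expect_equal(res$r, rep(1, 60), tolerance = 1e-12)
  expect_length(res$clusters, 1)
  expect_length(res$clusters[[1]], 60)
  expect_equal(res$p, 1 / 501)
  expect_error(instantaneous_correlation_test(th[1:3, ], th[1:3, ]),
               "4 participants")
})

test_that("cluster permutation test localizes effects and is label-stable", {
  withr::with_seed(18, {
    # global strong effect: one cluster covering the whole map
    maps <- matrix(rnorm(10 * 40, mean = 2), 10)
    ct <- cluster_permutation_test(maps, n_perm = 500, seed = 19)
    expect_length(ct$clusters, 1)
    expect_length(ct$clusters[[1]], 40)
    expect_true(ct$significant[1])
    # effect confined to rows 10:15 of a 2-D grid
    arr <- array(rnorm(12 * 30 * 10), c(12, 30, 10))
    arr[, 10:15, ] <- arr[, 10:15, ] + 1.2
    ct2 <- cluster_permutation_test(arr, n_perm = 500, seed = 20)
    sig_elems <- which(array(ct2$sig_mask, c(30, 10)), arr.ind = TRUE)
    expect_true(any(sig_elems[, 1] %in% 10:15))
    expect_true(all(sig_elems[, 1] %in% 8:17))
    # relabeling participants leaves p-values essentially unchanged
    maps3 <- matrix(rnorm(12 * 30), 12)
    maps3[, 5:12] <- maps3[, 5:12] + 1.3
    r1 <- cluster_permutation_test(maps3, n_perm = 2000, seed = 21)
    r2 <- cluster_permutation_test(maps3[sample(12), ], n_perm = 2000,
                                   seed = 21)
    expect_identical(r1$clusters, r2$clusters)
    expect_identical(r1$significant, r2$significant)
    expect_lt(max(abs(r1$p - r2$p)), 0.02)
  })
})

test_that("circular adjacency merges clusters across the wrap point", {
  withr::with_seed(22, {
    maps <- matrix(rnorm(10 * 60, 0, 0.3), 10)
    maps[, c(1:4, 57:60)] <- maps[, c(1:4, 57:60)] + 2
  })
  ct_lin <- cluster_permutation_test(maps, adjacency = "linear",
                                     n_perm = 300, seed = 22)
  ct_circ <- cluster_permutation_test(maps, adjacency = "circular",
                                      n_perm = 300, seed = 22)
  expect_gt(length(ct_lin$clusters), length(ct_circ$clusters))
  # one circular cluster spans the wrap: contains both bin 1 and bin 60
  spans <- vapply(ct_circ$clusters, function(cl) all(c(1, 60) %in% cl), TRUE)
  expect_true(any(spans))
})

test_that("lag scan is exact at zero shift and equivariant under shifts", {
  d <- sim_lagged_courses(-30, P = 12, seed = 23)
  ls1 <- lag_scan(d$al, d$th, n_null_per_lag = 0, engine = "fast",
                  grid = grid60)
  # zero shift reproduces the unshifted fit exactly
  i0 <- which(ls1$lags_deg == 0)
  fb <- harmonic_fixed_betas(d$th, d$al, grid = grid60)
  expect_equal(unname(ls1$beta[i0, "alpha"]), unname(fb$beta_w["alpha"]),
               tolerance = 1e-10)
  # equivariance: pre-shifting the power course shifts the whole profile
  k <- 4
  ls2 <- lag_scan(shift_courses_test(d$al, k), d$th, n_null_per_lag = 0,
                  engine = "fast", grid = grid60)
  expect_equal(circ_err_deg(ls2$peak_lag_deg,
                            ls1$peak_lag_deg - k * 6), 0)
  # blind-style recovery at course level (lmem engine)
  lsl <- lag_scan(d$al, d$th, n_null_per_lag = 50, engine = "lmem",
                  grid = grid60, seed = 24)
  expect_lte(abs(circ_err_deg(lsl$peak_lag_deg, -30)), 6)
  expect_equal(dim(lsl$null_v), c(60, 50))
})

test_that("bootstrap peak-lag CI is deterministic and degenerate when exact", {
  d <- sim_lagged_courses(-30, P = 8, seed = 25)
  b1 <- bootstrap_peak_lag(d$al, d$th, n_boot = 40, seed = 26,
                           grid = grid60)
  b2 <- bootstrap_peak_lag(d$al, d$th, n_boot = 40, seed = 26,
                           grid = grid60)
  expect_identical(b1$ci_deg, b2$ci_deg)
  expect_equal(b1$n_ok, 40)
  # identical participants: point-mass bootstrap distribution
  one <- sim_lagged_courses(-30, P = 1, seed = 27, noise = 0.2)
  thI <- one$th[rep(1, 8), ]
  alI <- one$al[rep(1, 8), ]
  bI <- bootstrap_peak_lag(alI, thI, n_boot = 25, seed = 28, grid = grid60)
  expect_equal(diff(bI$ci_deg), 0)
  expect_error(bootstrap_peak_lag(d$al[1:3, ], d$th[1:3, ]), "5 participants")
})
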