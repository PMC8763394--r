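# Harmonic mixed-effects modelling of phase-binned threshold courses:
# fixed sine/cosine (plus optional band-power regressors and interactions),
# per-participant random slopes with diagonal covariance, ML fitting so
# likelihood-ratio comparisons are valid, the respiratory phase-vector-norm
# permutation test, the instantaneous-correlation cluster test, the circular
# lag scan, and a bootstrap confidence interval for the peak lag.
#
# Permutation nulls and the fast lag-scan engine use the mean of
# per-participant OLS coefficients. For the balanced sine/cosine design
# (identical regressors for every participant) this equals the mixed model's
# ML fixed-effect estimate exactly; with power regressors it is the usual
# summary-statistics approximation (tested against the mixed model).

# long-format design from course matrices; power: named list of P x n mats
harmonic_design <- function(thresh, power = NULL, grid = phase_bin_grid()) {
  stopifnot(is.matrix(thresh), ncol(thresh) == grid$n)
  P <- nrow(thresh)
  w <- grid$centers
  d <- data.frame(
    T = as.vector(t(thresh)),
    pid = factor(rep(seq_len(P), each = grid$n)),
    sin_r = rep(sin(w), P),
    cos_r = rep(cos(w), P))
  if (!is.null(power)) {
    if (is.matrix(power)) power <- list(alpha = power)
    for (nm in names(power)) {
      stopifnot(all(dim(power[[nm]]) == dim(thresh)))
      d[[nm]] <- as.vector(t(power[[nm]]))
      d[[paste0("sin_", nm)]] <- d$sin_r * d[[nm]]
      d[[paste0("cos_", nm)]] <- d$cos_r * d[[nm]]
    }
    if (all(c("alpha", "beta") %in% names(power))) {
      d$alpha_beta <- d$alpha * d$beta
    }
  }
  d
}

harmonic_terms <- function(d) {
  base <- c("sin_r", "cos_r")
  extra <- setdiff(names(d), c("T", "pid", base))
  c(base, extra)
}

#' Fit a harmonic linear mixed-effects model
#'
#' Models z-scored threshold courses as a linear combination of sine and
#' cosine of the respiration phase and, optionally, z-scored band-power
#' courses with their sine/cosine interactions (and an alpha x beta
#' interaction when both bands are supplied). Every non-intercept fixed
#' effect gets a per-participant random slope with diagonal random-effects
#' covariance. Fitted by maximum likelihood.
#'
#' @param thresh participants x bins matrix of (z-scored) threshold courses.
#' @param power optional participants x bins matrix (alpha), or named list
#'   of such matrices (e.g. `list(alpha = ..., beta = ...)`).
#' @param grid a [phase_bin_grid()].
#' @return object of class `harmonic_lmem`: `beta`, `se`, `t`, `p`
#'   (residual-df convention `df = n_obs - n_fixed`), `df`, `loglik`,
#'   `ranef_var`, `sigma2`, `n_obs`, `n_fixed`, `terms`, and the fitted
#'   `model`.
#' @export
fit_harmonic_lmem <- function(thresh, power = NULL, grid = phase_bin_grid()) {
  if (nrow(thresh) < 3) stop("need at least 3 participants")
  d <- harmonic_design(thresh, power, grid)
  terms <- harmonic_terms(d)
  fml <- stats::as.formula(paste(
    "T ~", paste(terms, collapse = " + "), "+",
    paste(sprintf("(0 + %s | pid)", terms), collapse = " + ")))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore",
                            calc.derivs = FALSE)
  model <- suppressWarnings(suppressMessages(
    lme4::lmer(fml, data = d, REML = FALSE, control = ctrl)))
  b <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  n_obs <- nrow(d)
  n_fixed <- length(b)
  df <- n_obs - n_fixed
  tv <- b / se
  vc <- as.data.frame(lme4::VarCorr(model))
  rv <- stats::setNames(vc$vcov[is.na(vc$var2) & vc$grp != "Residual"],
                        vc$var1[is.na(vc$var2) & vc$grp != "Residual"])
  structure(list(beta = b, se = se, t = tv,
                 p = 2 * stats::pt(-abs(tv), df),
                 df = df, loglik = as.numeric(stats::logLik(model)),
                 ranef_var = rv,
                 sigma2 = stats::sigma(model)^2,
                 n_obs = n_obs, n_fixed = n_fixed,
                 terms = terms, model = model),
            class = "harmonic_lmem")
}

#' @export
print.harmonic_lmem <- function(x, ...) {
  cat(sprintf("<harmonic_lmem> %d obs, %d fixed effects, df = %d, logLik = %.2f\n",
              x$n_obs, x$n_fixed, x$df, x$loglik))
  tab <- data.frame(beta = x$beta, se = x$se, t = x$t, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Fast fixed-effect estimates from per-participant OLS fits
#'
#' Pools per-participant OLS coefficients across participants: the plain
#' mean (exact for the balanced sine/cosine design) and an inverse-variance
#' weighted mean with its standard error, which emulates the mixed model's
#' shrinkage when power regressors make some participants' designs nearly
#' collinear.
#'
#' @inheritParams fit_harmonic_lmem
#' @return list with `beta` (named, unweighted pooled), `beta_w` /
#'   `se_w` / `t_w` (inverse-variance weighted), `per_participant` (matrix),
#'   `terms`.
#' @export
harmonic_fixed_betas <- function(thresh, power = NULL,
                                 grid = phase_bin_grid()) {
  d <- harmonic_design(thresh, power, grid)
  terms <- harmonic_terms(d)
  P <- nrow(thresh)
  k <- length(terms) + 1
  B <- V <- matrix(NA_real_, P, k,
                   dimnames = list(NULL, c("(Intercept)", terms)))
  for (j in seq_len(P)) {
    rows <- ((j - 1) * grid$n + 1):(j * grid$n)
    X <- cbind(1, as.matrix(d[rows, terms, drop = FALSE]))
    f <- stats::lm.fit(X, d$T[rows])
    B[j, ] <- f$coefficients
    s2 <- sum(f$residuals^2) / max(1, f$df.residual)
    V[j, ] <- s2 * diag(chol2inv(chol(crossprod(X))))
  }
  # random-effects (DerSimonian-Laird style) pooling: per-term
  # between-participant variance added to each participant's OLS variance
  tau2 <- pmax(0, apply(B, 2, stats::var) - colMeans(V))
  W <- 1 / sweep(V, 2, tau2, "+")
  bw <- colSums(W * B) / colSums(W)
  sew <- sqrt(1 / colSums(W))
  list(beta = colMeans(B), beta_w = bw, se_w = sew, t_w = bw / sew,
       per_participant = B, terms = c("(Intercept)", terms))
}

#' Respiratory phase vector norm
#'
#' @param beta_sin,beta_cos harmonic regression weights.
#' @return list with `v = sqrt(beta_sin^2 + beta_cos^2)` and the implied
#'   modulation `phase = atan2(beta_sin, beta_cos)` (radians, the phase at
#'   which the fitted harmonic peaks).
#' @export
vector_norm <- function(beta_sin, beta_cos) {
  stopifnot(is.finite(beta_sin), is.finite(beta_cos))
  list(v = sqrt(beta_sin^2 + beta_cos^2),
       phase = atan2(beta_sin, beta_cos))
}

#' Permutation test of the respiratory phase vector norm
#'
#' The empirical sine/cosine weights of the harmonic model are combined into
#' `v = sqrt(b_sin^2 + b_cos^2)` and compared against a null distribution
#' obtained by independently shuffling each participant's course across bins
#' and refitting (`n_perm` times). Because the sine/cosine design is
#' balanced and identical across participants, the refit uses the exact
#' closed-form fixed-effect estimate (mean per-participant OLS).
#'
#' @param thresh participants x bins matrix of z-scored threshold courses.
#' @param n_perm number of within-participant shuffles.
#' @param grid a [phase_bin_grid()].
#' @param seed integer seed.
#' @return object of class `vector_norm_test`: `v`, `phase`, `null` (vector
#'   of null norms), `p` (add-one rule), `n_perm`.
#' @export
permutation_vector_norm_test <- function(thresh, n_perm = 5000,
                                         grid = phase_bin_grid(), seed = 1) {
  stopifnot(n_perm >= 100)
  w <- grid$centers
  X <- cbind(1, sin(w), cos(w))
  proj <- X %*% solve(crossprod(X)) # n_bins x 3; betas = Y %*% proj
  emp <- colMeans(thresh %*% proj)
  vn <- vector_norm(emp[2], emp[3])
  P <- nrow(thresh)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    Yp <- thresh
    for (j in seq_len(P)) Yp[j, ] <- Yp[j, sample.int(ncol(thresh))]
    b <- colMeans(Yp %*% proj)
    sqrt(b[2]^2 + b[3]^2)
  }, 0))
  structure(list(v = vn$v, phase = vn$phase, null = null,
                 p = (1 + sum(null >= vn$v)) / (n_perm + 1),
                 n_perm = n_perm),
            class = "vector_norm_test")
}

#' @export
print.vector_norm_test <- function(x, ...) {
  cat(sprintf("<vector_norm_test> v = %.4f, phase = %.1f deg, p = %.4g (%d perms)\n",
              x$v, x$phase * 180 / pi, x$p, x$n_perm))
  invisible(x)
}

#' Likelihood-ratio comparison of nested harmonic mixed models
#'
#' @param reduced,full `harmonic_lmem` fits on identical data, fixed effects
#'   of `reduced` nested in `full`.
#' @return list with `chisq = 2 * (ll_full - ll_reduced)`, `df` (difference
#'   in fixed-effect count), `p`.
#' @export
lrt_compare <- function(reduced, full) {
  stopifnot(inherits(reduced, "harmonic_lmem"), inherits(full, "harmonic_lmem"))
  if (reduced$n_obs != full$n_obs) {
    stop("models were not fit on identical data")
  }
  if (setequal(reduced$terms, full$terms)) {
    return(list(chisq = 0, df = 0, p = 1)) # identical designs
  }
  if (!all(reduced$terms %in% full$terms) ||
      full$n_fixed <= reduced$n_fixed) {
    stop("models are not nested (reduced fixed effects must be a strict subset)")
  }
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- full$n_fixed - reduced$n_fixed
  list(chisq = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Instantaneous power-threshold correlation with cluster correction
#'
#' Correlates, per phase bin, band power with threshold across participants
#' (Pearson r), forms clusters of contiguous bins with one-tailed p < 0.05
#' and positive r, sums r within clusters, and builds the null by shuffling
#' the participant order of the power matrix (`n_perm` times), storing the
#' maximal null cluster mass.
#'
#' @param power,thresh participants x bins matrices (matched rows).
#' @param n_perm permutations of the participant order.
#' @param alpha cluster significance level (one-tailed).
#' @param cluster_alpha element-wise threshold (one-tailed).
#' @param adjacency `"circular"` (default: phase is a circle) or `"linear"`.
#' @param seed integer seed.
#' @return list of class `instant_corr_test`: `r` (per bin), `clusters`,
#'   `masses`, `p`, `significant`, `sig_mask`, `null_max`.
#' @export
instantaneous_correlation_test <- function(power, thresh, n_perm = 10000,
                                           alpha = 0.05,
                                           cluster_alpha = 0.05,
                                           adjacency = "circular", seed = 1) {
  stopifnot(all(dim(power) == dim(thresh)))
  n <- nrow(power)
  if (n < 4) stop("need at least 4 participants for correlation")
  nb <- ncol(power)
  Pz <- scale(power); Tz <- scale(thresh)
  # zero-variance bins would poison the correlation; flag them
  Pz[!is.finite(Pz)] <- 0; Tz[!is.finite(Tz)] <- 0
  rvec <- colSums(Pz * Tz) / (n - 1)
  rcrit <- {
    tc <- stats::qt(1 - cluster_alpha, n - 2)
    tc / sqrt(n - 2 + tc^2)
  }
  circ <- adjacency == "circular"
  cl <- runs_1d(rvec >= rcrit, circular = circ)
  masses <- vapply(cl, function(i) sum(rvec[i]), 0)
  null_max <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    rp <- colSums(Pz[sample.int(n), ] * Tz) / (n - 1)
    cp <- runs_1d(rp >= rcrit, circular = circ)
    if (length(cp)) max(vapply(cp, function(i) sum(rp[i]), 0)) else 0
  }, 0))
  pvals <- vapply(masses, function(m) {
    (1 + sum(null_max >= m)) / (n_perm + 1)
  }, 0)
  sig <- pvals <= alpha
  mask <- logical(nb)
  for (i in which(sig)) mask[cl[[i]]] <- TRUE
  structure(list(r = rvec, clusters = cl, masses = masses, p = pvals,
                 significant = sig, sig_mask = mask, null_max = null_max,
                 n_perm = n_perm),
            class = "instant_corr_test")
}

# circularly shift each row of a course matrix by k bins:
# shifted[, i] = original[, i + k] (indices wrap)
shift_courses <- function(m, k) {
  nb <- ncol(m)
  idx <- ((seq_len(nb) - 1 + k) %% nb) + 1
  m[, idx, drop = FALSE]
}

#' Circular lag scan of the power effect on threshold courses
#'
#' For each of the 60 lags (step pi/30), the power course of every
#' participant is circularly shifted against the threshold course and the
#' harmonic model with sine, cosine, power and interactions is refit; beta
#' and t values of every predictor are stored per lag. A per-lag null
#' distribution of the respiratory vector norm is built by shuffling each
#' participant's threshold course. The peak lag is the lag of the maximal
#' power t value (ties broken toward smaller absolute lag).
#'
#' @param power,thresh participants x bins matrices.
#' @param n_null_per_lag null iterations per lag (0 to skip).
#' @param engine `"lmem"` (mixed model per lag) or `"fast"` (mean
#'   per-participant OLS with a one-sample t across participants).
#' @param grid a [phase_bin_grid()].
#' @param seed integer seed.
#' @return object of class `lag_scan_result`: `lags_rad`, `lags_deg`,
#'   `beta` / `t` (lag x predictor matrices), `null_v` (lag x n_null), and
#'   `peak_lag_deg`.
#' @export
lag_scan <- function(power, thresh, n_null_per_lag = 1000,
                     engine = c("lmem", "fast"), grid = phase_bin_grid(),
                     seed = 1) {
  engine <- match.arg(engine)
  stopifnot(all(dim(power) == dim(thresh)), ncol(power) == grid$n)
  nb <- grid$n
  P <- nrow(power)
  shifts <- seq_len(nb) - 1
  lags <- wrap_angle(shifts * grid$step)
  ord <- order(lags)
  shifts <- shifts[ord]; lags <- lags[ord]
  terms <- c("(Intercept)", "sin_r", "cos_r", "alpha", "sin_alpha",
             "cos_alpha")
  bmat <- tmat <- matrix(NA_real_, nb, length(terms),
                         dimnames = list(NULL, terms))
  null_v <- if (n_null_per_lag > 0) matrix(NA_real_, nb, n_null_per_lag)
            else NULL
  for (li in seq_len(nb)) {
    pw <- shift_courses(power, shifts[li])
    if (engine == "lmem") {
      fit <- fit_harmonic_lmem(thresh, pw, grid)
      bmat[li, ] <- fit$beta[terms]
      tmat[li, ] <- fit$t[terms]
    } else {
      fb <- harmonic_fixed_betas(thresh, pw, grid)
      bmat[li, ] <- fb$beta_w[terms]
      tmat[li, ] <- fb$t_w[terms]
    }
    if (n_null_per_lag > 0) {
      # per-participant OLS projectors for the shifted design
      w <- grid$centers
      projs <- lapply(seq_len(P), function(j) {
        X <- cbind(1, sin(w), cos(w), pw[j, ], sin(w) * pw[j, ],
                   cos(w) * pw[j, ])
        solve(crossprod(X), t(X)) # 6 x nb
      })
      null_v[li, ] <- with_seed(derive_seed(seed, paste0("lag", li)), {
        vapply(seq_len(n_null_per_lag), function(it) {
          bs <- 0; bc <- 0
          for (j in seq_len(P)) {
            y <- thresh[j, sample.int(nb)]
            bj <- projs[[j]] %*% y
            bs <- bs + bj[2]; bc <- bc + bj[3]
          }
          sqrt((bs / P)^2 + (bc / P)^2)
        }, 0)
      })
    }
  }
  t_alpha <- tmat[, "alpha"]
  best <- which(t_alpha == max(t_alpha))
  peak <- best[which.min(abs(lags[best]))]
  structure(list(lags_rad = lags, lags_deg = rad2deg(lags),
                 beta = bmat, t = tmat, null_v = null_v,
                 peak_lag_deg = rad2deg(lags[peak]),
                 peak_index = peak, engine = engine),
            class = "lag_scan_result")
}

#' @export
print.lag_scan_result <- function(x, ...) {
  cat(sprintf("<lag_scan_result> %d lags (%s engine), peak alpha effect at %+.0f deg (t = %.2f)\n",
              length(x$lags_rad), x$engine, x$peak_lag_deg,
              x$t[x$peak_index, "alpha"]))
  invisible(x)
}

#' Bootstrap confidence interval for the peak lag
#'
#' Resamples participants with replacement, reruns the lag scan per
#' resample, and reports circular percentiles of the peak-lag distribution.
#'
#' @param power,thresh participants x bins matrices (>= 5 participants).
#' @param n_boot bootstrap iterations.
#' @param engine lag-scan engine (default `"fast"`; the mixed-model engine
#'   is exact but orders of magnitude slower).
#' @param probs CI percentiles.
#' @param grid a [phase_bin_grid()].
#' @param seed integer seed.
#' @return list with `ci_deg`, `peak_lags_deg`, `center_deg`, `n_ok`.
#' @export
bootstrap_peak_lag <- function(power, thresh, n_boot = 500,
                               engine = "fast", probs = c(0.025, 0.975),
                               grid = phase_bin_grid(), seed = 1) {
  P <- nrow(power)
  if (P < 5) stop("need at least 5 participants to bootstrap")
  peaks <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- with_seed(derive_seed(seed, paste0("boot", b)),
                     sample.int(P, P, replace = TRUE))
    res <- tryCatch(
      lag_scan(power[idx, , drop = FALSE], thresh[idx, , drop = FALSE],
               n_null_per_lag = 0, engine = engine, grid = grid),
      error = function(e) NULL)
    if (!is.null(res)) peaks[b] <- deg2rad(res$peak_lag_deg)
  }
  ok <- which(!is.na(peaks))
  if (length(ok) < 0.9 * n_boot) {
    stop("more than 10% of bootstrap iterations failed")
  }
  pk <- peaks[ok]
  ctr <- circ_mean(pk)
  dev <- wrap_angle(pk - ctr)
  ci <- ctr + stats::quantile(dev, probs, names = FALSE)
  list(ci_deg = rad2deg(ci), peak_lags_deg = rad2deg(pk),
       center_deg = rad2deg(ctr), n_ok = length(ok))
}
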