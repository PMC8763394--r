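# Psychometric fitting: Bayesian grid fit of the 3AFC cumulative-Gaussian
# psychometric function (guess fixed at 1/3), and the moving-window
# phase-resolved threshold refit in which width and lapse stay fixed at the
# overall estimates and the threshold gets a Gaussian prior from the overall
# posterior.

#' Detection probability of a fitted psychometric function
#'
#' @param contrast contrast vector.
#' @param fit a `psych_fit` (or any list with threshold/width/guess/lapse).
#' @return detection probability `guess + (1-guess-lapse) * Phi((c-T)/w)`.
#' @export
psychf_prob <- function(contrast, fit) {
  fit$guess + (1 - fit$guess - fit$lapse) *
    stats::pnorm((contrast - fit$threshold) / fit$width)
}

# Bernoulli log-likelihood of detection data for given p(detect) columns
ll_bernoulli <- function(P, detected) {
  colSums(log(P[detected, , drop = FALSE])) +
    colSums(log1p(-P[!detected, , drop = FALSE]))
}

#' Fit the overall psychometric function
#'
#' Bayesian fit on a log-threshold x log-width x lapse grid with Bernoulli
#' likelihood `p(c) = guess + (1 - guess - lapse) * Phi((c - T) / width)`.
#' Priors are flat on log-threshold and log-width over a data-driven span and
#' flat on lapse over \[0, lapse_max\]; point estimates are posterior means.
#'
#' @param contrasts per-trial contrast (target trials).
#' @param detected per-trial logical detection outcome.
#' @param guess fixed guess rate (1/3 for 3AFC).
#' @param lapse_max upper bound of the lapse grid.
#' @param grid_n grid points per continuous parameter.
#' @param lapse_n grid points for the lapse.
#' @return object of class `psych_fit`: threshold, width, lapse, guess,
#'   `threshold_sd` (posterior SD of the threshold), `n_trials`.
#' @export
fit_psychf <- function(contrasts, detected, guess = 1 / 3, lapse_max = 0.1,
                       grid_n = 101, lapse_n = 11) {
  stopifnot(length(contrasts) == length(detected))
  ok <- is.finite(contrasts) & !is.na(detected)
  contrasts <- contrasts[ok]; detected <- as.logical(detected[ok])
  if (length(contrasts) < 20) stop("need at least 20 trials to fit")
  if (all(detected) || !any(detected)) {
    stop("threshold unidentifiable: all trials have the same outcome")
  }
  cmed <- stats::median(contrasts)
  tgrid <- exp(seq(log(cmed / 4), log(cmed * 4), length.out = grid_n))
  wgrid <- exp(seq(log(cmed / 100), log(cmed * 2), length.out = grid_n))
  lgrid <- seq(0, lapse_max, length.out = lapse_n)
  ll <- array(NA_real_, c(grid_n, grid_n, lapse_n))
  for (iw in seq_len(grid_n)) {
    P <- stats::pnorm(outer(contrasts, tgrid, "-") / wgrid[iw])
    for (il in seq_len(lapse_n)) {
      pd <- guess + (1 - guess - lgrid[il]) * P
      ll[, iw, il] <- ll_bernoulli(pd, detected)
    }
  }
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  pT <- apply(post, 1, sum)
  pW <- apply(post, 2, sum)
  pL <- apply(post, 3, sum)
  thr <- sum(tgrid * pT)
  structure(list(threshold = thr,
                 width = sum(wgrid * pW),
                 lapse = sum(lgrid * pL),
                 guess = guess,
                 threshold_sd = sqrt(max(0, sum(tgrid^2 * pT) - thr^2)),
                 n_trials = length(contrasts)),
            class = "psych_fit")
}

#' @export
print.psych_fit <- function(x, ...) {
  cat(sprintf(
    "<psych_fit> threshold %.4f (sd %.4f), width %.4f, lapse %.3f, guess %.3f (n=%d)\n",
    x$threshold, x$threshold_sd, x$width, x$lapse, x$guess, x$n_trials))
  invisible(x)
}

# circular linear interpolation of NA entries in a length-n course
circ_interp_na <- function(x) {
  n <- length(x)
  bad <- which(is.na(x))
  if (!length(bad)) return(x)
  good <- which(!is.na(x))
  if (length(good) < 2) stop("too few populated bins to interpolate")
  for (i in bad) {
    # nearest populated neighbors in circular index distance
    dprev <- (i - good) %% n
    dnext <- (good - i) %% n
    p <- good[which.min(ifelse(dprev == 0, n, dprev))]
    q <- good[which.min(ifelse(dnext == 0, n, dnext))]
    dp <- (i - p) %% n; dq <- (q - i) %% n
    x[i] <- (x[p] * dq + x[q] * dp) / (dp + dq)
  }
  x
}

#' Refit the threshold per respiration-phase bin
#'
#' For each of the 60 moving-window bins, selects the hit/miss trials whose
#' phase lies within center +/- pi/10 and refits the threshold only (width
#' and lapse fixed at the overall estimates) on a log-threshold grid with a
#' Gaussian prior centered at the overall threshold. Bins with fewer than
#' `min_trials` trials are imputed by circular linear interpolation. The
#' course is finally z-scored across bins.
#'
#' @param contrasts,detected,phases per-trial data (analyzed target trials,
#'   hits and misses only).
#' @param overall a `psych_fit` from [fit_psychf()].
#' @param grid a [phase_bin_grid()].
#' @param min_trials minimum trials for a bin to be fit directly.
#' @param prior_scale multiplier on the overall posterior threshold SD to set
#'   the refit prior SD.
#' @param grid_n threshold grid points.
#' @param max_empty_frac maximal tolerated fraction of under-populated bins.
#' @return object of class `threshold_course`: `threshold` (raw, length 60),
#'   `threshold_z`, `n_trials` per bin, `imputed` mask, `grid`.
#' @export
refit_threshold_by_phase <- function(contrasts, detected, phases, overall,
                                     grid = phase_bin_grid(),
                                     min_trials = 15, prior_scale = 2,
                                     grid_n = 101, max_empty_frac = 0.2) {
  stopifnot(inherits(overall, "psych_fit"))
  bins <- phase_binning(phases, grid)
  n_per <- lengths(bins)
  if (mean(n_per < min_trials) > max_empty_frac) {
    stop("more than ", round(100 * max_empty_frac),
         "% of phase bins are under-populated; collect more trials")
  }
  prior_sd <- max(overall$threshold_sd * prior_scale,
                  1e-3 * overall$threshold)
  rel <- prior_sd / overall$threshold
  tgrid <- overall$threshold * exp(seq(-4 * rel, 4 * rel,
                                       length.out = grid_n))
  logprior <- stats::dnorm(tgrid, overall$threshold, prior_sd, log = TRUE)
  fit_bin <- function(idx) {
    d <- as.logical(detected[idx])
    if (all(d) || !any(d)) return(NA_real_)
    P <- overall$guess + (1 - overall$guess - overall$lapse) *
      stats::pnorm(outer(contrasts[idx], tgrid, "-") / overall$width)
    lp <- ll_bernoulli(P, d) + logprior
    w <- exp(lp - max(lp)); w <- w / sum(w)
    sum(tgrid * w)
  }
  vals <- rep(NA_real_, grid$n)
  for (b in seq_len(grid$n)) {
    if (n_per[b] >= min_trials) vals[b] <- fit_bin(bins[[b]])
  }
  imputed <- is.na(vals)
  vals <- circ_interp_na(vals)
  structure(list(threshold = vals,
                 threshold_z = as.numeric(zscore_safe(vals)),
                 n_trials = n_per, imputed = imputed, grid = grid),
            class = "threshold_course")
}

#' Grand-average threshold course
#'
#' Bin-wise mean and SEM across participants' z-scored courses.
#'
#' @param courses list of `threshold_course` objects (or a participants x
#'   bins matrix of z-scored courses).
#' @return list with `mean`, `sem`, `n`, `grid` (when available).
#' @export
grand_average_course <- function(courses) {
  if (is.matrix(courses)) {
    m <- courses
    grid <- NULL
  } else {
    lens <- vapply(courses, function(cc) length(cc$threshold_z), 0L)
    if (length(unique(lens)) != 1) stop("mismatched course grids")
    m <- do.call(rbind, lapply(courses, function(cc) cc$threshold_z))
    grid <- courses[[1]]$grid
  }
  if (nrow(m) < 2) stop("need at least 2 participants")
  list(mean = colMeans(m),
       sem = apply(m, 2, stats::sd) / sqrt(nrow(m)),
       n = nrow(m), grid = grid)
}

#' Stack threshold or power courses into a participants x bins matrix
#'
#' @param courses list of `threshold_course` objects or numeric vectors.
#' @param what `"z"` for z-scored values, `"raw"` for raw thresholds.
#' @return numeric matrix, participants in rows.
#' @export
course_matrix <- function(courses, what = c("z", "raw")) {
  what <- match.arg(what)
  rows <- lapply(courses, function(cc) {
    if (inherits(cc, "threshold_course")) {
      if (what == "z") cc$threshold_z else cc$threshold
    } else as.numeric(cc)
  })
  do.call(rbind, rows)
}
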