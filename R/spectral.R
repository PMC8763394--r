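# Time-frequency machinery: analytic Morlet transform (frequency-domain
# Gaussian with Heaviside cutoff, i.e. a one-sided filter), amplitude
# envelopes with moving-average smoothing, DPSS multitaper TFRs, the
# phase-triggered average, the phase-binned power course, and the
# surrogate-normalized phase-amplitude modulation index.

#' Analytic Morlet wavelet transform
#'
#' Frequency-domain implementation: the signal spectrum is multiplied by a
#' Gaussian centered on each target frequency and zeroed at non-positive
#' frequencies (Heaviside), then inverse-transformed, yielding an analytic
#' (complex) band-limited signal per frequency. The filter gain is 2 at the
#' center frequency so a unit-amplitude cosine has unit envelope.
#'
#' @param signal uniformly sampled numeric vector.
#' @param fs sampling rate in Hz.
#' @param freqs center frequencies in Hz (must lie in (0, fs/2)).
#' @param n_cycles wavelet width in cycles (time-frequency trade-off).
#' @return complex matrix, `length(freqs)` x `length(signal)`.
#' @export
morlet_transform <- function(signal, fs, freqs, n_cycles = 6) {
  n <- length(signal)
  if (any(freqs <= 0 | freqs >= fs / 2)) {
    stop("frequencies must lie strictly inside (0, Nyquist)")
  }
  X <- stats::fft(signal)
  f_axis <- (seq_len(n) - 1) / n * fs
  f_axis[f_axis > fs / 2] <- f_axis[f_axis > fs / 2] - fs # signed axis
  out <- matrix(0i, length(freqs), n)
  for (i in seq_along(freqs)) {
    fc <- freqs[i]
    sigma_f <- fc / n_cycles
    g <- 2 * exp(-(f_axis - fc)^2 / (2 * sigma_f^2))
    g[f_axis <= 0] <- 0 # Heaviside: suppress negative frequencies
    out[i, ] <- stats::fft(X * g, inverse = TRUE) / n
  }
  out
}

# centered moving average with shrinking edge windows, row-wise
moving_average_rows <- function(m, L) {
  if (L <= 1) return(m)
  n <- ncol(m)
  hw_l <- (L - 1) %/% 2
  hw_r <- L - 1 - hw_l
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  lo <- pmax(seq_len(n) - hw_l, 1)
  hi <- pmin(seq_len(n) + hw_r, n)
  sw <- cs[, hi + 1, drop = FALSE] - cs[, lo, drop = FALSE]
  sweep(sw, 2, hi - lo + 1, "/")
}

#' Amplitude envelope of complex wavelet coefficients
#'
#' Magnitude followed by a centered boxcar of `round(smooth * fs)` samples;
#' the window shrinks at the edges so a constant input is preserved exactly.
#'
#' @param coeffs complex matrix (freq x time) or vector.
#' @param fs sampling rate in Hz.
#' @param smooth smoothing window length in seconds (0 for none).
#' @return numeric matrix of smoothed amplitude envelopes.
#' @export
amplitude_envelope <- function(coeffs, fs, smooth = 0.3) {
  stopifnot(smooth >= 0)
  m <- if (is.matrix(coeffs)) Mod(coeffs) else matrix(Mod(coeffs), nrow = 1)
  moving_average_rows(m, round(smooth * fs))
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the symmetric tridiagonal formulation of the Slepian
#' eigenproblem; tapers are unit-energy and ordered by concentration.
#'
#' @param n taper length in samples.
#' @param nw time-half-bandwidth product.
#' @param k number of tapers.
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, k >= 1, k <= n)
  w <- nw / n
  i <- seq_len(n) - 1
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- i[-1] * (n - i[-1]) / 2
  A[cbind(2:n, 1:(n - 1))] <- off
  A[cbind(1:(n - 1), 2:n)] <- off
  e <- eigen(A, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  tap <- sweep(tap, 2, sqrt(colSums(tap^2)), "/")
  # sign convention: positive mean (even orders) / positive initial slope
  for (j in seq_len(k)) {
    s <- sum(tap[, j])
    if ((abs(s) > 1e-8 && s < 0) || (abs(s) <= 1e-8 && tap[2, j] < 0)) {
      tap[, j] <- -tap[, j]
    }
  }
  tap
}

#' Multitaper time-frequency representation
#'
#' DPSS multitaper power over a moving window (default 500 ms, stepped by
#' 50 ms), with a 2 Hz spectral smoothing below `smooth_split` Hz and 5 Hz
#' above, mirroring common practice for prestimulus power analyses.
#'
#' @param epochs numeric array trials x channels x samples (a matrix is
#'   interpreted as trials x samples with one channel).
#' @param fs sampling rate in Hz.
#' @param times per-sample time axis in seconds (default starts at
#'   `t_start`).
#' @param freqs analysis frequencies in Hz.
#' @param win window length in seconds.
#' @param step window step in seconds.
#' @param smooth_low,smooth_high spectral half-smoothing in Hz below/above
#'   `smooth_split`.
#' @param smooth_split frequency (Hz) separating the two smoothing regimes.
#' @param t_start time of the first sample (used when `times` is NULL).
#' @param time_range restrict output window centers to this range (seconds).
#' @return list with `power` (trials x channels x freq x time), `freqs`,
#'   `times` (window centers).
#' @export
multitaper_tfr <- function(epochs, fs, times = NULL, freqs = 5:40,
                           win = 0.5, step = 0.05,
                           smooth_low = 2, smooth_high = 5,
                           smooth_split = 30, t_start = -1.25,
                           time_range = c(-1, 0.2)) {
  if (is.matrix(epochs)) {
    epochs <- array(epochs, c(nrow(epochs), 1, ncol(epochs)))
  }
  dt <- dim(epochs)
  n_trials <- dt[1]; n_chan <- dt[2]; n_samp <- dt[3]
  if (is.null(times)) times <- t_start + (seq_len(n_samp) - 1) / fs
  L <- round(win * fs)
  if (L > n_samp) stop("analysis window longer than the epoch")
  hw <- L %/% 2
  centers_idx <- seq(hw + 1, n_samp - (L - hw - 1), by = max(1, round(step * fs)))
  tc <- times[centers_idx]
  keep <- tc >= time_range[1] - 1e-9 & tc <= time_range[2] + 1e-9
  centers_idx <- centers_idx[keep]; tc <- tc[keep]
  if (!length(centers_idx)) stop("no analysis windows inside time_range")
  nfft <- max(L, round(fs)) # zero-pad to ~1 s for a 1 Hz frequency grid
  f_axis <- (seq_len(nfft) - 1) * fs / nfft
  fbin <- vapply(freqs, function(f) which.min(abs(f_axis - f)), 0L)
  smooth <- ifelse(freqs < smooth_split, smooth_low, smooth_high)
  pw <- array(0, c(n_trials, n_chan, length(freqs), length(centers_idx)))
  for (sm in unique(smooth)) {
    k <- max(1, floor(2 * sm * win - 1))
    tap <- dpss_tapers(L, sm * win, k)
    fsel <- which(smooth == sm)
    for (ti in seq_along(centers_idx)) {
      sel <- (centers_idx[ti] - hw):(centers_idx[ti] - hw + L - 1)
      for (tr in seq_len(n_trials)) {
        for (ch in seq_len(n_chan)) {
          seg <- epochs[tr, ch, sel]
          acc <- 0
          for (kk in seq_len(k)) {
            sp <- stats::fft(c(seg * tap[, kk], numeric(nfft - L)))
            acc <- acc + Mod(sp[fbin[fsel]])^2
          }
          pw[tr, ch, fsel, ti] <- acc / k
        }
      }
    }
  }
  list(power = pw, freqs = freqs, times = tc)
}

#' Subsample hits to the miss count and contrast conditions
#'
#' Randomly subsamples hit-trial maps without replacement to match the
#' number of miss trials (avoiding trial-count bias), then returns the
#' mean(hit) - mean(miss) difference map.
#'
#' @param hit_maps,miss_maps arrays with trials in the first dimension
#'   (e.g. trial-wise TFR power).
#' @param seed integer seed for the subsample.
#' @return the difference array (first dimension dropped).
#' @export
match_and_contrast <- function(hit_maps, miss_maps, seed = 1) {
  hd <- dim(hit_maps); md <- dim(miss_maps)
  if (is.null(hd)) { hit_maps <- matrix(hit_maps, ncol = 1); hd <- dim(hit_maps) }
  if (is.null(md)) { miss_maps <- matrix(miss_maps, ncol = 1); md <- dim(miss_maps) }
  n_hit <- hd[1]; n_miss <- md[1]
  if (n_miss < 1) stop("need at least one miss trial")
  if (n_hit < n_miss) stop("fewer hits than misses; nothing to subsample")
  idx <- if (n_hit == n_miss) seq_len(n_hit) else {
    with_seed(seed, sample.int(n_hit, n_miss))
  }
  flat_h <- matrix(hit_maps, nrow = n_hit)
  flat_m <- matrix(miss_maps, nrow = n_miss)
  d <- colMeans(flat_h[idx, , drop = FALSE]) - colMeans(flat_m)
  if (length(hd) > 2) array(d, hd[-1]) else d
}

#' Phase-triggered average of band-limited power
#'
#' Averages the per-frequency amplitude envelope within windows of
#' `halfwin` samples around each peak-inspiration event, then z-scores each
#' frequency row across time. Constant rows are returned as zeros and
#' flagged.
#'
#' @param envelopes numeric matrix freq x time.
#' @param phase a `phase_series` (peaks taken from its extrema).
#' @param halfwin half window length in samples (window = 2 * halfwin).
#' @return matrix freq x (2 * halfwin) with attribute `degenerate_rows`.
#' @export
phase_triggered_average <- function(envelopes, phase, halfwin) {
  if (!is.matrix(envelopes)) envelopes <- matrix(envelopes, nrow = 1)
  n <- ncol(envelopes)
  peaks <- phase$extrema$peak
  usable <- peaks[peaks - halfwin >= 1 & peaks + halfwin - 1 <= n]
  if (length(usable) < 3) stop("fewer than 3 usable peaks for the PTA")
  acc <- matrix(0, nrow(envelopes), 2 * halfwin)
  dimnames(envelopes) <- NULL
  off <- (-halfwin):(halfwin - 1)
  for (p in usable) acc <- acc + envelopes[, p + off, drop = FALSE]
  acc <- acc / length(usable)
  degen <- logical(nrow(acc))
  for (i in seq_len(nrow(acc))) {
    s <- stats::sd(acc[i, ])
    if (s == 0) { acc[i, ] <- 0; degen[i] <- TRUE }
    else acc[i, ] <- (acc[i, ] - mean(acc[i, ])) / s
  }
  attr(acc, "degenerate_rows") <- degen
  attr(acc, "n_peaks") <- length(usable)
  acc
}

#' Phase-binned power course
#'
#' Band-averages the envelope (rows within `band` when `freqs` are given),
#' then takes the mean over samples falling in each moving-window phase bin
#' and z-scores across bins. Empty bins are circularly interpolated and
#' flagged.
#'
#' @param envelope numeric vector, or matrix freq x time with `freqs`.
#' @param phase a `phase_series` on the same sampling grid.
#' @param grid a [phase_bin_grid()].
#' @param band optional c(f_lo, f_hi) in Hz to average over.
#' @param freqs per-row frequencies of `envelope` (required with `band`).
#' @return z-scored course of length `grid$n` with attributes `raw` (mean
#'   envelope per bin) and `imputed`.
#' @export
bin_power_by_phase <- function(envelope, phase, grid = phase_bin_grid(),
                               band = NULL, freqs = NULL) {
  if (is.matrix(envelope)) {
    if (!is.null(band)) {
      stopifnot(!is.null(freqs), length(freqs) == nrow(envelope))
      sel <- freqs >= band[1] & freqs <= band[2]
      if (!any(sel)) stop("no envelope rows inside the requested band")
      envelope <- colMeans(envelope[sel, , drop = FALSE])
    } else envelope <- colMeans(envelope)
  }
  stopifnot(length(envelope) == length(phase$phase))
  bins <- phase_binning(phase$phase, grid)
  raw <- vapply(bins, function(i) {
    if (length(i)) mean(envelope[i]) else NA_real_
  }, 0)
  imputed <- is.na(raw)
  raw <- circ_interp_na(raw)
  z <- as.numeric(zscore_safe(raw))
  attr(z, "raw") <- raw
  attr(z, "imputed") <- imputed
  z
}

# raw entropy-based modulation index of binned amplitudes (rows = signals)
mi_from_binmeans <- function(bm) {
  apply(bm, 1, function(m) {
    m[is.na(m)] <- 0
    if (all(m <= 0)) return(NA_real_)
    p <- m / sum(m)
    p <- p[p > 0]
    h <- -sum(p * log(p))
    (log(ncol(bm)) - h) / log(ncol(bm))
  })
}

#' Surrogate-normalized phase-amplitude modulation index
#'
#' Mean amplitude in 20 equal respiration-phase bins is normalized to a
#' distribution whose entropic deviation from uniform gives the raw
#' modulation index `(log N - H) / log N` in \[0, 1\]. Bias is removed by
#' normalizing against `n_surr` circular time shifts of the phase series:
#' `normalized = (raw - mean(surrogates)) / sd(surrogates)`.
#'
#' @param envelope amplitude vector, or matrix freq x time.
#' @param phase a `phase_series`.
#' @param n_bins number of equal-width phase bins.
#' @param n_surr number of circular-shift surrogates.
#' @param seed integer seed.
#' @param min_shift_s minimum surrogate shift in seconds.
#' @return list of class `mi_result`: `raw`, `surrogate_mean`,
#'   `surrogate_sd`, `normalized` (per row of `envelope`), `n_bins`,
#'   `n_surr`.
#' @export
modulation_index <- function(envelope, phase, n_bins = 20, n_surr = 200,
                             seed = 1, min_shift_s = 1) {
  if (!is.matrix(envelope)) envelope <- matrix(envelope, nrow = 1)
  valid <- which(phase$valid)
  if (!length(valid)) stop("phase undefined everywhere")
  env <- envelope[, valid, drop = FALSE]
  if (all(env == 0)) stop("all-zero envelope")
  ph <- phase$phase[valid]
  nt <- length(ph)
  # left-open right-closed equal bins over (-pi, pi]
  ka <- pmin(n_bins, floor((ph + pi) / (2 * pi / n_bins)) + 1L)
  ka[ph <= -pi] <- 1L
  binmeans <- function(kvec) {
    sums <- rowsum(t(env), kvec)
    cnt <- tabulate(kvec, n_bins)
    bm <- matrix(NA_real_, nrow(env), n_bins)
    got <- sort(unique(kvec))
    bm[, got] <- t(sums / cnt[got])
    bm
  }
  raw <- mi_from_binmeans(binmeans(ka))
  min_shift <- min(round(min_shift_s * phase$fs), nt %/% 4)
  surr <- with_seed(seed, {
    offs <- sample(seq(min_shift, nt - min_shift), n_surr, replace = TRUE)
    vapply(offs, function(o) {
      kb <- ka[((seq_len(nt) - 1 + o) %% nt) + 1]
      mi_from_binmeans(binmeans(kb))
    }, numeric(nrow(env)))
  })
  surr <- matrix(surr, nrow = nrow(env))
  sm <- rowMeans(surr)
  ssd <- apply(surr, 1, stats::sd)
  structure(list(raw = raw, surrogate_mean = sm, surrogate_sd = ssd,
                 normalized = (raw - sm) / ssd,
                 n_bins = n_bins, n_surr = n_surr),
            class = "mi_result")
}

#' Group-level cluster test of normalized modulation indices
#'
#' One-tailed t-tests of participant MI values at each frequency against the
#' 95th percentile of the surrogate null, thresholded at `cluster_alpha`,
#' with cluster-sum significance from sign-flip permutations of the centered
#' values.
#'
#' @param mi_matrix participants x frequencies normalized MI values.
#' @param null_q95 per-frequency 95th percentile of the null distribution
#'   (on the same normalized scale; scalar recycled).
#' @param n_perm permutation iterations.
#' @param alpha cluster significance level.
#' @param cluster_alpha element-wise threshold.
#' @param seed integer seed.
#' @return a `cluster_test_result` (see [cluster_permutation_test()]).
#' @export
mi_group_test <- function(mi_matrix, null_q95, n_perm = 5000, alpha = 0.05,
                          cluster_alpha = 0.05, seed = 1) {
  stopifnot(nrow(mi_matrix) >= 2)
  centered <- sweep(mi_matrix, 2, rep_len(null_q95, ncol(mi_matrix)))
  cluster_permutation_test(centered, adjacency = "linear", n_perm = n_perm,
                           alpha = alpha, cluster_alpha = cluster_alpha,
                           tail = "pos", seed = seed)
}
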