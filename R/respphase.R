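# Respiration phase extraction: alternating peak/trough detection with
# persistence pruning, piecewise-linear phase interpolation (trough -> peak
# covers -pi -> 0, peak -> trough covers 0 -> pi), the Welch-style breathing
# spectrum, and the 60-bin moving-window phase grid shared by all downstream
# stages.

#' Detect alternating respiration peaks and troughs
#'
#' Candidate extrema (including trace endpoints) are pruned in two passes:
#' persistence pruning removes adjacent peak/trough pairs whose amplitude
#' difference is below `prominence` (smallest first), then a minimum
#' same-type distance of `min_cycle / 2` is enforced between consecutive
#' peaks (and troughs), dropping the weaker extremum and one intervening
#' opposite-type extremum so the sequence stays strictly alternating.
#'
#' @param trace a [respiration_trace()].
#' @param min_cycle minimum plausible breathing cycle duration in seconds;
#'   same-type extrema closer than `min_cycle / 2` are merged.
#' @param prominence minimum peak-to-adjacent-trough amplitude difference in
#'   z-units.
#' @return list with integer sample indices `peak` and `trough`, plus the
#'   combined `index`/`type` sequence in temporal order.
#' @export
detect_extrema <- function(trace, min_cycle = 3.85, prominence = 0.5) {
  stopifnot(inherits(trace, "respiration_trace"), min_cycle > 0)
  x <- trace$samples
  n <- length(x)
  if (n < 2 * min_cycle * trace$fs) {
    stop("trace too short for extrema detection at this min_cycle")
  }
  d <- diff(x)
  s <- sign(d)
  # resolve flat stretches by carrying the previous slope forward
  for (i in which(s == 0)) s[i] <- if (i > 1) s[i - 1] else 1
  turn <- which(diff(s) != 0) + 1L
  idx <- c(1L, turn, n)
  type <- integer(length(idx)) # +1 peak, -1 trough
  type[1] <- if (s[1] > 0) -1L else 1L
  if (length(turn)) {
    type[2:(length(turn) + 1)] <- ifelse(s[turn] < 0, 1L, -1L)
  }
  type[length(idx)] <- if (s[n - 1] > 0) 1L else -1L
  if (length(idx) < 3) stop("no extrema found in trace")
  # collapse runs of same-type extrema, keeping the most extreme
  keep <- rep(TRUE, length(idx))
  i <- 1
  while (i < length(idx)) {
    j <- i + 1
    while (j <= length(idx) && type[j] == type[i]) j <- j + 1
    if (j - i > 1) {
      run <- i:(j - 1)
      best <- run[which.max(type[i] * x[idx[run]])]
      keep[setdiff(run, best)] <- FALSE
    }
    i <- j
  }
  idx <- idx[keep]; type <- type[keep]
  min_sep <- min_cycle / 2 * trace$fs
  repeat {
    changed <- FALSE
    # persistence pruning: weakest adjacent peak/trough pair first
    repeat {
      if (length(idx) < 3) break
      dv <- abs(diff(x[idx]))
      bad <- which(dv < prominence)
      if (!length(bad)) break
      k <- bad[which.min(dv[bad])]
      idx <- idx[-c(k, k + 1)]; type <- type[-c(k, k + 1)]
      changed <- TRUE
    }
    # same-type minimum distance (peak-to-peak / trough-to-trough)
    if (length(idx) >= 3) {
      gaps <- idx[-(1:2)] - idx[seq_len(length(idx) - 2)]
      bad <- which(gaps < min_sep)
      if (length(bad)) {
        k <- bad[1] # extrema k and k+2 share a type and are too close
        weaker <- if (type[k] * x[idx[k]] < type[k] * x[idx[k + 2]]) k
                  else k + 2
        drop <- if (weaker == k) c(k, k + 1) else c(k + 1, k + 2)
        idx <- idx[-drop]; type <- type[-drop]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  interior <- idx > 1 & idx < n
  if (!any(interior)) stop("no extrema found in trace")
  list(peak = idx[type == 1L], trough = idx[type == -1L],
       index = idx, type = ifelse(type == 1L, "peak", "trough"))
}

#' Interpolate respiration phase between extrema
#'
#' Phase runs linearly from -pi at a trough to 0 at the following peak
#' (inspiration) and from 0 to +pi from peak to trough (expiration). Samples
#' before the first or after the last detected extremum have undefined phase
#' (NA) and are excluded from all binning.
#'
#' @param trace a [respiration_trace()].
#' @param extrema output of [detect_extrema()].
#' @return an object of class `phase_series`: list with `fs`, `phase`
#'   (per-sample angle in (-pi, pi\], NA where undefined), `extrema`, and
#'   `valid` (logical mask).
#' @export
interpolate_phase <- function(trace, extrema) {
  stopifnot(inherits(trace, "respiration_trace"))
  idx <- extrema$index
  type <- extrema$type
  if (length(idx) < 2) stop("need at least 2 extrema to interpolate phase")
  if (any(type[-1] == type[-length(type)])) {
    stop("extrema must strictly alternate")
  }
  n <- length(trace$samples)
  phase <- rep(NA_real_, n)
  for (k in seq_len(length(idx) - 1)) {
    a <- idx[k]; b <- idx[k + 1]
    sel <- a:b
    frac <- (sel - a) / (b - a)
    if (type[k] == "trough") {
      phase[sel] <- -pi + pi * frac   # inspiration: -pi -> 0
    } else {
      phase[sel] <- pi * frac         # expiration: 0 -> pi
    }
  }
  phase[!is.na(phase)] <- wrap_angle(phase[!is.na(phase)])
  structure(list(fs = trace$fs, phase = phase,
                 extrema = extrema, valid = !is.na(phase)),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d samples @ %g Hz, %d peaks / %d troughs\n",
              length(x$phase), x$fs, length(x$extrema$peak),
              length(x$extrema$trough)))
  invisible(x)
}

#' Breathing power spectrum (0-2 Hz)
#'
#' Welch-style estimate: 20 s segments with 50% overlap, linear detrend,
#' single Hann taper, zero-padding to 40 s (0.025 Hz frequency increment),
#' averaged across segments.
#'
#' @param trace a [respiration_trace()].
#' @param seg_len segment length in seconds.
#' @param pad_len zero-padded segment length in seconds.
#' @param fmax upper frequency bound in Hz.
#' @return list with `freq` (Hz), `power`, and `dominant_freq` (argmax of
#'   power over (0, fmax\]).
#' @export
breathing_spectrum <- function(trace, seg_len = 20, pad_len = 40, fmax = 2) {
  stopifnot(inherits(trace, "respiration_trace"))
  fs <- trace$fs
  x <- trace$samples
  nseg <- round(seg_len * fs)
  if (length(x) < nseg) {
    stop(sprintf("trace shorter than one %g s segment", seg_len))
  }
  nfft <- round(pad_len * fs)
  step <- nseg %/% 2
  starts <- seq(1, length(x) - nseg + 1, by = step)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  tt <- seq_len(nseg)
  acc <- numeric(nfft)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1)]
    fitc <- stats::lm.fit(cbind(1, tt), seg)$coefficients
    seg <- seg - (fitc[1] + fitc[2] * tt)
    padded <- c(seg * taper, numeric(nfft - nseg))
    acc <- acc + Mod(stats::fft(padded))^2
  }
  acc <- acc / length(starts)
  freq <- (seq_len(nfft) - 1) * fs / nfft
  keep <- freq <= fmax + 1e-9
  freq <- freq[keep]; pw <- acc[keep]
  pos <- freq > 0
  dom <- freq[pos][which.max(pw[pos])]
  list(freq = freq, power = pw, dominant_freq = dom)
}

#' The 60-bin moving-window phase grid
#'
#' Bin centers step by pi/30 from -pi to pi - pi/30; each bin's membership
#' window is its center +/- pi/10, so windows overlap and wrap circularly
#' across +/-pi.
#'
#' @param n number of bins.
#' @param halfwidth half-width of each bin's membership window (radians).
#' @return an object of class `phase_bin_grid` with `centers`, `halfwidth`,
#'   `step` and `n`.
#' @export
phase_bin_grid <- function(n = 60, halfwidth = pi / 10) {
  step <- 2 * pi / n
  structure(list(centers = -pi + step * (seq_len(n) - 1),
                 halfwidth = halfwidth, step = step, n = n),
            class = "phase_bin_grid")
}

#' Assign angles to overlapping phase bins
#'
#' An angle belongs to a bin iff its circular distance to the bin center is
#' at most the grid half-width (boundary inclusive); bins near +/-pi wrap.
#'
#' @param angles angles in radians (wrapped internally); NA angles belong to
#'   no bin.
#' @param grid a [phase_bin_grid()].
#' @return list of integer index vectors, one per bin.
#' @export
phase_binning <- function(angles, grid = phase_bin_grid()) {
  stopifnot(inherits(grid, "phase_bin_grid"))
  a <- wrap_angle(angles)
  lapply(grid$centers, function(ct) {
    which(!is.na(a) & circ_dist(a, ct) <= grid$halfwidth + 1e-9)
  })
}
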