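# Synthetic cohort generator: quasi-periodic respiration, a staircase-driven
# observer whose detection threshold depends on respiration phase, and band
# power whose amplitude is coupled to respiration phase at a known lag.
# Ground truth is carried along so downstream recovery can be tested.

#' Construct a respiration trace object
#'
#' @param samples amplitude vector (z-units after normalization).
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @return an object of class `respiration_trace`.
#' @export
respiration_trace <- function(samples, fs, t0 = 0) {
  stopifnot(fs > 0, is.numeric(samples))
  if (any(!is.finite(samples))) stop("non-finite samples in respiration trace")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "respiration_trace")
}

#' @export
print.respiration_trace <- function(x, ...) {
  cat(sprintf("<respiration_trace> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Generate a quasi-periodic respiration trace
#'
#' Concatenates raised-cosine half-cycles (trough to peak, peak to trough)
#' with independently jittered durations, so the signal is non-sinusoidal and
#' asymmetric while its generative phase is exactly known. The trace is
#' z-scored after adding amplitude noise.
#'
#' @param params a [respiration_params()] object.
#' @param duration trace duration in seconds (must cover >= 2 mean cycles).
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return a `respiration_trace` with attributes `true_phase` (per-sample
#'   generative phase in (-pi, pi\]), `true_extrema` (list of peak/trough
#'   sample indices) and `params`.
#' @export
gen_respiration <- function(params = respiration_params(), duration, fs,
                            seed = 1) {
  stopifnot(inherits(params, "respiration_params"), duration > 0, fs > 0)
  min_dur <- 2 / params$mean_rate
  if (duration < min_dur) {
    stop(sprintf("duration %.2f s too short: need at least %.2f s (2 cycles)",
                 duration, min_dur))
  }
  with_seed(seed, {
    cyc <- 1 / params$mean_rate
    n_cycles <- ceiling(duration / cyc) + 10L
    f <- params$inspiration_fraction
    jit <- function(mu, n) {
      if (params$rate_cv == 0) return(rep(mu, n))
      # lognormal jitter: positive support, right-skewed like real breathing
      s2 <- log(1 + params$rate_cv^2)
      stats::rlnorm(n, log(mu) - s2 / 2, sqrt(s2))
    }
    insp <- jit(f * cyc, n_cycles)
    expd <- jit((1 - f) * cyc, n_cycles)
    # half-cycle boundary times: trough, peak, trough, peak, ...
    half <- as.vector(rbind(insp, expd))
    bounds <- c(0, cumsum(half))
    n <- floor(duration * fs)
    t <- (seq_len(n) - 1) / fs
    idx <- findInterval(t, bounds, rightmost.closed = TRUE)
    idx[idx < 1] <- 1L
    idx[idx > length(half)] <- length(half)
    frac <- (t - bounds[idx]) / half[idx]
    frac <- pmin(pmax(frac, 0), 1)
    # odd half-cycles are inspiration (-pi -> 0), even are expiration (0 -> pi)
    phase <- ifelse(idx %% 2 == 1, -pi + pi * frac, pi * frac)
    phase <- wrap_angle(phase)
    x <- cos(phase)
    if (params$amp_noise_sd > 0) {
      # band-limited (slow) amplitude noise: smoothed white noise rescaled,
      # emulating belt drift/wobble rather than sample-wise sensor noise
      w <- stats::rnorm(n)
      L <- max(1, round(0.5 * fs))
      w <- moving_average_rows(matrix(w, 1), L)[1, ]
      x <- x + w * params$amp_noise_sd / stats::sd(w)
    }
    x <- as.numeric(scale(x))
    tr <- respiration_trace(x, fs)
    bt <- bounds[bounds < duration]
    bi <- round(bt * fs) + 1
    keep <- bi >= 1 & bi <= n
    types <- rep(c("trough", "peak"), length.out = length(bt))[keep]
    bi <- bi[keep]
    attr(tr, "true_phase") <- phase
    attr(tr, "true_extrema") <- list(peak = bi[types == "peak"],
                                     trough = bi[types == "trough"])
    attr(tr, "params") <- params
    tr
  })
}

#' Simulate observer responses for a set of trials
#'
#' Detection probability on target trials follows the 3AFC cumulative-Gaussian
#' model with a phase-dependent threshold; detected targets are reported on
#' the correct side (up to `wrong_side_rate`), undetected targets and
#' unnoticed catch trials as "none".
#'
#' @param contrast per-trial contrast (NA on catch trials).
#' @param phase per-trial respiration phase in radians.
#' @param side per-trial true side: "left", "right" or "none".
#' @param obs an [observer_params()] object.
#' @param seed integer seed (ignored if `use_rng = TRUE`).
#' @param use_rng if TRUE, draw from the current RNG stream instead of
#'   re-seeding (used inside the staircase loop).
#' @param extra_threshold per-trial additive threshold offset (contrast
#'   units), e.g. the excitability pathway driven by band power.
#' @return character vector of responses in `{left, right, none}`.
#' @export
simulate_observer_trials <- function(contrast, phase, side, obs, seed = 1,
                                     use_rng = FALSE, extra_threshold = 0) {
  stopifnot(inherits(obs, "observer_params"))
  n <- max(length(contrast), length(phase), length(side))
  contrast <- rep_len(as.numeric(contrast), n)
  phase <- rep_len(as.numeric(phase), n)
  side <- rep_len(side, n)
  extra_threshold <- rep_len(as.numeric(extra_threshold), n)
  if (any(contrast < 0, na.rm = TRUE)) stop("negative contrast")
  if (any(!is.finite(phase))) stop("non-finite phase")
  body <- function() {
    thr <- obs$threshold_base + extra_threshold +
      obs$threshold_mod_amp * cos(phase - obs$threshold_mod_phase)
    p_det <- obs$guess + (1 - obs$guess - obs$lapse) *
      stats::pnorm((contrast - thr) / obs$width)
    resp <- rep("none", n)
    tgt <- side != "none"
    det <- tgt & stats::runif(n) < p_det
    resp[det] <- side[det]
    if (obs$wrong_side_rate > 0) {
      flip <- det & stats::runif(n) < obs$wrong_side_rate
      resp[flip] <- ifelse(side[flip] == "left", "right", "left")
    }
    if (obs$false_alarm_rate > 0) {
      fa <- !tgt & stats::runif(n) < obs$false_alarm_rate
      resp[fa] <- sample(c("left", "right"), sum(fa), replace = TRUE)
    }
    resp
  }
  if (use_rng) body() else with_seed(seed, body())
}

#' True detection probability of the simulated observer
#'
#' @inheritParams simulate_observer_trials
#' @return detection probability vector.
#' @export
observer_detection_prob <- function(contrast, phase, obs) {
  thr <- obs$threshold_base +
    obs$threshold_mod_amp * cos(phase - obs$threshold_mod_phase)
  obs$guess + (1 - obs$guess - obs$lapse) *
    stats::pnorm((contrast - thr) / obs$width)
}

#' Generate respiration-coupled band power
#'
#' Envelope model: `baseline_amp * (1 + mod_depth * cos(phase - phi)) + noise`
#' with `phi` the effective coupling phase. Optionally also returns a raw
#' oscillation, `envelope * cos(2*pi*f*t + phi0)` over a 1/f background.
#'
#' @param phase per-sample respiration phase (radians).
#' @param coupling a [coupling_params()] object.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param coupling_phase effective coupling phase override (radians); default
#'   uses `coupling$coupling_phase`.
#' @param mod_depth modulation depth override (default `coupling$mod_depth`).
#' @param return_raw if TRUE, also synthesize the raw oscillatory signal.
#' @return list with `envelope` (strictly positive vector) and, when
#'   requested, `raw`. The envelope noise is band-limited with timescale
#'   `coupling$env_noise_tau` seconds.
#' @export
gen_coupled_power <- function(phase, coupling, fs, seed = 1,
                              coupling_phase = NULL, mod_depth = NULL,
                              return_raw = FALSE) {
  stopifnot(inherits(coupling, "coupling_params"))
  m <- if (is.null(mod_depth)) coupling$mod_depth else mod_depth
  if (m >= 1) stop("mod_depth >= 1 would give a negative envelope")
  if (any(!is.finite(phase))) stop("phase must be defined at every sample")
  phi <- if (is.null(coupling_phase)) coupling$coupling_phase else coupling_phase
  n <- length(phase)
  with_seed(seed, {
    env <- coupling$baseline_amp * (1 + m * cos(phase - phi))
    if (coupling$env_noise_sd > 0) {
      w <- stats::rnorm(n)
      L <- max(1, round(coupling$env_noise_tau * fs))
      if (L > 1) w <- moving_average_rows(matrix(w, 1), L)[1, ]
      env <- env + w / stats::sd(w) * coupling$env_noise_sd *
        coupling$baseline_amp
    }
    env <- pmax(env, 1e-9 * coupling$baseline_amp)
    out <- list(envelope = env)
    if (return_raw) {
      t <- (seq_len(n) - 1) / fs
      phi0 <- stats::runif(1, -pi, pi)
      raw <- env * cos(2 * pi * coupling$center_freq * t + phi0)
      raw <- raw + pink_noise(n, coupling$noise_exponent) *
        0.5 * coupling$baseline_amp
      out$raw <- raw
    }
    out
  })
}

# 1/f^alpha noise via spectral shaping, unit variance
pink_noise <- function(n, alpha = 1) {
  nf <- n %/% 2
  f <- seq_len(nf)
  amp <- f^(-alpha / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) full[nf + 1] <- complex(real = Mod(full[nf + 1]))
  full[n:(n - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE))
  as.numeric(scale(x))
}

#' Generate a full synthetic cohort
#'
#' For each participant: jittered observer and coupling parameters, `n_runs`
#' respiration traces, a per-run QUEST session over the configured trial mix,
#' and phase-binned band-power courses (60-bin moving-window grid) derived
#' from respiration-coupled envelopes. Fully determined by `config$seed`.
#'
#' @param config a [cohort_config()] object.
#' @param keep_traces if TRUE, retain per-run respiration traces (memory!).
#' @return a list of class `cohort` with elements `participants` (each with
#'   `trials` data frame, `power_courses` matrix bins x bands, and optional
#'   `traces`), `grid` (the phase-bin grid), `ground_truth` (per-participant
#'   generative parameters) and `config`.
#' @export
gen_cohort <- function(config = cohort_config(), keep_traces = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  grid <- phase_bin_grid()
  gt <- vector("list", config$n_participants)
  parts <- vector("list", config$n_participants)
  bands <- vapply(config$coupling, function(cp) cp$band, "")
  for (j in seq_len(config$n_participants)) {
    sj <- derive_seed(config$seed, paste0("participant", j))
    pars <- with_seed(sj, {
      ob <- config$observer
      ob$threshold_base <- ob$threshold_base *
        (1 + stats::rnorm(1, 0, config$jitter$threshold_base_rel))
      ob$threshold_mod_phase <- wrap_angle(ob$threshold_mod_phase +
        stats::rnorm(1, 0, deg2rad(config$jitter$mod_phase_sd_deg)))
      # shared modulation-strength factor: participants with stronger
      # behavioral phase modulation also show deeper power modulation
      shared <- max(-0.8, stats::rnorm(1, 0,
                                       config$jitter$mod_amp_shared_rel))
      ob$threshold_mod_amp <- ob$threshold_mod_amp * (1 + shared)
      depths <- vapply(config$coupling, function(cp) {
        min(0.95, max(0, cp$mod_depth * (1 + shared)))
      }, 0)
      cps <- lapply(config$coupling, function(cp) {
        # power maximum aligns with the threshold maximum (alpha power and
        # threshold covary positively) shifted by the configured lag
        base_phi <- if (!is.null(cp$lag_deg)) {
          ob$threshold_mod_phase + deg2rad(cp$lag_deg)
        } else cp$coupling_phase
        wrap_angle(base_phi +
          stats::rnorm(1, 0, deg2rad(config$jitter$coupling_phase_sd_deg)))
      })
      list(observer = ob, phis = cps, depths = depths, shared = shared)
    })
    trials_list <- list()
    env_all <- lapply(bands, function(b) list())
    phase_all <- list()
    traces <- list()
    for (r in seq_len(config$n_runs)) {
      sr <- derive_seed(config$seed, sprintf("p%d_run%d", j, r))
      run_dur <- config$trials_per_run * config$iti + 12
      tr <- gen_respiration(config$respiration, run_dur, config$fs,
                            seed = derive_seed(sr, "resp"))
      ph <- attr(tr, "true_phase")
      onsets <- with_seed(derive_seed(sr, "onsets"), {
        gaps <- stats::runif(config$trials_per_run,
                             0.8 * config$iti, 1.2 * config$iti)
        5 + cumsum(gaps)
      })
      sides <- with_seed(derive_seed(sr, "sides"), {
        n_catch <- round(config$catch_fraction * config$trials_per_run)
        n_tgt <- config$trials_per_run - n_catch
        n_left <- n_tgt %/% 2
        sample(c(rep("left", n_left), rep("right", n_tgt - n_left),
                 rep("none", n_catch)))
      })
      ph_tr <- ph[pmin(round(onsets * config$fs) + 1, length(ph))]
      # band envelopes, plus the excitability pathway: the z-scored envelope,
      # read out at a phase-domain lag (power fluctuations at respiration
      # phase w influence the threshold at phase w - lag), feeds into the
      # observer's momentary threshold
      uph <- unwrap_phase(ph)
      extra <- numeric(length(ph))
      for (b in seq_along(bands)) {
        cp <- config$coupling[[b]]
        pw <- gen_coupled_power(ph, cp, config$fs,
                                seed = derive_seed(sr, paste0("pow", b)),
                                coupling_phase = pars$phis[[b]],
                                mod_depth = pars$depths[b])
        env_all[[b]][[r]] <- pw$envelope
        if (cp$behav_gain != 0) {
          lag_rad <- wrap_angle(pars$phis[[b]] -
                                  pars$observer$threshold_mod_phase)
          ez <- as.numeric(scale(pw$envelope))
          idx <- stats::approx(uph, seq_along(uph), xout = uph + lag_rad,
                               rule = 2)$y
          extra <- extra + cp$behav_gain * ez[round(idx)]
        }
      }
      extra_tr <- extra[pmin(round(onsets * config$fs) + 1, length(ph))]
      tt <- run_quest_session(pars$observer, ph_tr,
                              target_hr = config$target_hr,
                              sides = sides,
                              seed = derive_seed(sr, "quest"),
                              extra_threshold = extra_tr)
      tt$run <- r
      tt$onset_s <- onsets
      trials_list[[r]] <- tt
      phase_all[[r]] <- ph
      if (keep_traces) traces[[r]] <- tr
    }
    trials <- do.call(rbind, trials_list)
    trials$trial <- seq_len(nrow(trials))
    ph_cat <- unlist(phase_all)
    pc <- vapply(seq_along(bands), function(b) {
      course_from_envelope(unlist(env_all[[b]]), ph_cat, grid)
    }, numeric(grid$n))
    colnames(pc) <- bands
    parts[[j]] <- list(id = j, trials = trials, power_courses = pc,
                       traces = if (keep_traces) traces else NULL)
    gt[[j]] <- list(threshold_base = pars$observer$threshold_base,
                    threshold_mod_amp = pars$observer$threshold_mod_amp,
                    threshold_mod_phase = pars$observer$threshold_mod_phase,
                    coupling_phase = vapply(pars$phis, identity, 0),
                    mod_depths = pars$depths,
                    shared_scaling = pars$shared)
  }
  structure(list(participants = parts, grid = grid, ground_truth = gt,
                 config = config),
            class = "cohort")
}

# moving-window phase-binned mean of an envelope, z-scored across bins
course_from_envelope <- function(env, phase, grid) {
  m <- vapply(grid$centers, function(ct) {
    mean(env[circ_dist(phase, ct) <= grid$halfwidth])
  }, 0)
  as.numeric(zscore_safe(m))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d runs x %d trials, seed %d\n",
              x$config$n_participants, x$config$n_runs,
              x$config$trials_per_run, x$config$seed))
  invisible(x)
}
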