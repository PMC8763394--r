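# QUEST adaptive staircase (Watson-Pelli scheme): grid posterior over log10
# threshold, Weibull likelihood with gamma = 1/3, placement and estimate at
# the posterior mean. The staircase is self-correcting: at its stationary
# point the observer's hit rate at the placement intensity equals the target,
# regardless of moderate mismatch between the assumed Weibull and the
# observer's true (cumulative-Gaussian) psychometric shape.

quest_psi <- function(d, beta, gamma, delta) {
  gamma + (1 - gamma - delta) * (1 - exp(-10^(beta * d)))
}

# offset of the target-performance point from the threshold parameter
quest_offset <- function(target, beta, gamma, delta) {
  q <- (target - gamma) / (1 - gamma - delta)
  log10(-log(1 - q)) / beta
}

quest_init <- function(guess_log10, prior_sd = 0.7, grid_span = 4,
                       grid_n = 401L, beta = 3.5, gamma = 1 / 3,
                       delta = 0.02) {
  tgrid <- seq(guess_log10 - grid_span * prior_sd,
               guess_log10 + grid_span * prior_sd, length.out = grid_n)
  logpost <- stats::dnorm(tgrid, guess_log10, prior_sd, log = TRUE)
  list(tgrid = tgrid, logpost = logpost - max(logpost),
       beta = beta, gamma = gamma, delta = delta)
}

quest_mean <- function(q) {
  w <- exp(q$logpost - max(q$logpost))
  sum(q$tgrid * w) / sum(w)
}

quest_update <- function(q, x_log10, detected) {
  p <- quest_psi(x_log10 - q$tgrid, q$beta, q$gamma, q$delta)
  q$logpost <- q$logpost + if (detected) log(p) else log1p(-p)
  q$logpost <- q$logpost - max(q$logpost)
  q
}

#' Run one QUEST session against a simulated observer
#'
#' Target-trial contrast is placed at the posterior-mean threshold estimate
#' shifted to the target-performance point of the assumed Weibull; catch
#' trials carry no contrast and do not inform the staircase.
#'
#' @param obs an [observer_params()] object (the generative observer).
#' @param phase_at_trial per-trial respiration phase in radians.
#' @param target_hr staircase target hit rate, in `(guess, 1 - lapse)`.
#' @param sides optional per-trial side vector ("left"/"right"/"none");
#'   default alternates left/right targets with no catch trials.
#' @param seed integer seed.
#' @param initial_guess initial threshold guess in contrast units
#'   (default: the observer's baseline threshold).
#' @param prior_sd prior SD on log10 threshold.
#' @param beta,delta Weibull slope and lapse assumed by the staircase.
#' @param contrast_max upper clip for placed contrasts.
#' @param extra_threshold per-trial additive threshold offset passed to the
#'   observer (excitability pathway; recycled).
#' @return a data.frame (TrialTable) with columns `trial`, `side`, `contrast`
#'   (NA on catch), `response`, `phase`, `detected`, `quest_estimate`.
#' @export
run_quest_session <- function(obs, phase_at_trial, target_hr = 0.60,
                              sides = NULL, seed = 1,
                              initial_guess = obs$threshold_base,
                              prior_sd = 0.7, beta = 3.5, delta = 0.02,
                              contrast_max = 1, extra_threshold = 0) {
  stopifnot(inherits(obs, "observer_params"))
  n <- length(phase_at_trial)
  extra_threshold <- rep_len(extra_threshold, n)
  if (target_hr <= obs$guess || target_hr >= 1 - obs$lapse) {
    stop(sprintf("target_hr %.2f outside attainable range (%.3f, %.3f)",
                 target_hr, obs$guess, 1 - obs$lapse))
  }
  if (is.null(sides)) sides <- rep(c("left", "right"), length.out = n)
  stopifnot(length(sides) == n, all(sides %in% c("left", "right", "none")))
  with_seed(seed, {
    q <- quest_init(log10(initial_guess), prior_sd = prior_sd, beta = beta,
                    gamma = obs$guess, delta = delta)
    d0 <- quest_offset(target_hr, beta, obs$guess, delta)
    contrast <- rep(NA_real_, n)
    response <- character(n)
    detected <- rep(NA, n)
    estimate <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      est <- quest_mean(q)
      estimate[i] <- 10^est
      if (sides[i] == "none") {
        response[i] <- simulate_observer_trials(NA, phase_at_trial[i],
                                                "none", obs, use_rng = TRUE,
                                                extra_threshold =
                                                  extra_threshold[i])
      } else {
        x <- min(est + d0, log10(contrast_max))
        contrast[i] <- 10^x
        response[i] <- simulate_observer_trials(contrast[i],
                                                phase_at_trial[i], sides[i],
                                                obs, use_rng = TRUE,
                                                extra_threshold =
                                                  extra_threshold[i])
        detected[i] <- response[i] == sides[i]
        q <- quest_update(q, x, detected[i])
      }
    }
    data.frame(trial = seq_len(n), side = sides, contrast = contrast,
               response = response, phase = phase_at_trial,
               detected = detected, quest_estimate = estimate,
               stringsAsFactors = FALSE)
  })
}
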