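# Pipeline orchestration: one configuration drives simulate-or-load,
# behavioral MI, phase-resolved psychometric refitting, harmonic mixed
# models with permutation nulls, the instantaneous-correlation cluster test,
# the lag scan, and (optionally) the phase-amplitude coupling stage; all
# randomness fans out from a single master seed via named substreams.

#' Analysis configuration
#'
#' @param simulate a [cohort_config()] describing the synthetic cohort (used
#'   when no input paths are given).
#' @param inputs optional list of input paths per participant (advanced;
#'   each element a list with `trials` CSV and `trace` TSV paths).
#' @param bands named list of frequency bands in Hz, e.g.
#'   `list(alpha = c(8, 13), beta = c(14, 30))`.
#' @param discard_first staircase burn-in trials discarded per run.
#' @param n_perm_vector permutations for the vector-norm test.
#' @param n_perm_corr permutations for the instantaneous-correlation test.
#' @param n_perm_cluster permutations for cluster tests on courses.
#' @param n_null_per_lag null iterations per lag in the lag scan.
#' @param n_boot bootstrap iterations for the peak-lag CI.
#' @param alpha significance level.
#' @param lag_engine `"fast"` or `"lmem"` (see [lag_scan()]).
#' @param run_pac whether to run the modulation-index stage.
#' @param pac_n_surr surrogates per modulation index.
#' @param seed master seed (overrides `simulate$seed`).
#' @param out_dir optional output directory for the results bundle.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(simulate = cohort_config(), inputs = NULL,
                            bands = list(alpha = c(8, 13),
                                         beta = c(14, 30)),
                            discard_first = 20, n_perm_vector = 5000,
                            n_perm_corr = 10000, n_perm_cluster = 5000,
                            n_null_per_lag = 1000, n_boot = 500,
                            alpha = 0.05, lag_engine = "fast",
                            run_pac = FALSE, pac_n_surr = 200,
                            seed = simulate$seed, out_dir = NULL) {
  structure(list(simulate = simulate, inputs = inputs, bands = bands,
                 discard_first = discard_first,
                 n_perm_vector = n_perm_vector, n_perm_corr = n_perm_corr,
                 n_perm_cluster = n_perm_cluster,
                 n_null_per_lag = n_null_per_lag, n_boot = n_boot,
                 alpha = alpha, lag_engine = lag_engine,
                 run_pac = run_pac, pac_n_surr = pac_n_surr,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "analysis_config")
}

#' Hash of the semantically meaningful configuration fields
#'
#' @param config an [analysis_config()] or any list.
#' @return hex string; changes iff any field value changes.
#' @export
config_hash <- function(config) {
  config$out_dir <- NULL # output location does not alter the analysis
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  h1 <- 0; h2 <- 0
  for (ch in utf8ToInt(as.character(s))) {
    h1 <- (h1 * 131 + ch) %% 2147483647
    h2 <- (h2 * 137 + ch) %% 2147483629
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

#' Validate pipeline inputs
#'
#' Checks column schemas, sampling uniformity, phase range, positive target
#' contrasts and monotone onsets. Reports issues; never throws.
#'
#' @param trials TrialTable data.frame (or NULL).
#' @param trace a `respiration_trace` or 2-column time/amplitude data.frame
#'   (or NULL).
#' @return data.frame with columns `field` and `issue` (zero rows if clean).
#' @export
validate_inputs <- function(trials = NULL, trace = NULL) {
  issues <- list()
  note <- function(field, issue) {
    issues[[length(issues) + 1]] <<- data.frame(field = field, issue = issue)
  }
  if (!is.null(trials)) {
    need <- c("side", "contrast", "response")
    miss <- setdiff(need, names(trials))
    if (length(miss)) note("trials", paste("missing columns:",
                                           paste(miss, collapse = ", ")))
    if (all(need %in% names(trials))) {
      tgt <- trials$side %in% c("left", "right")
      if (any(tgt & (!is.finite(trials$contrast) | trials$contrast <= 0))) {
        note("trials", "nonpositive contrast on a target trial")
      }
      if (!all(trials$side %in% c("left", "right", "none"))) {
        note("trials", "side outside {left, right, none}")
      }
      if (!all(trials$response %in% c("left", "right", "none"))) {
        note("trials", "response outside {left, right, none}")
      }
    }
    if (!is.null(trials$phase) &&
        any(abs(trials$phase) > pi + 1e-9, na.rm = TRUE)) {
      note("trials", "phase outside (-pi, pi]")
    }
    if (!is.null(trials$onset_s) && !is.null(trials$run)) {
      for (r in unique(trials$run)) {
        on <- trials$onset_s[trials$run == r]
        if (is.unsorted(on, strictly = TRUE)) {
          note("trials", paste("non-monotone onsets in run", r))
          break
        }
      }
    }
  }
  if (!is.null(trace)) {
    if (is.data.frame(trace)) {
      if (ncol(trace) < 2) {
        note("trace", "expected 2 columns (time_s, amplitude)")
      } else {
        dt <- diff(trace[[1]])
        if (length(dt) && (max(dt) > 2.5 * stats::median(dt))) {
          note("trace", "non-uniform sampling (gap > 2 samples)")
        }
        if (any(!is.finite(trace[[2]]))) note("trace", "non-finite amplitude")
      }
    } else if (inherits(trace, "respiration_trace")) {
      if (any(!is.finite(trace$samples))) note("trace", "non-finite amplitude")
    }
  }
  if (!length(issues)) {
    data.frame(field = character(0), issue = character(0))
  } else do.call(rbind, issues)
}

#' Assign respiration phase to trial onsets
#'
#' @param trials TrialTable with `onset_s`.
#' @param phase a `phase_series`.
#' @return `trials` with a `phase` column (NA where phase is undefined).
#' @export
assign_trial_phase <- function(trials, phase) {
  idx <- pmin(pmax(round(trials$onset_s * phase$fs) + 1, 1),
              length(phase$phase))
  trials$phase <- phase$phase[idx]
  trials
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: simulate (or load) the cohort; classify
#' trials and compute hit rates; GCMI phase-gain model comparison;
#' phase-resolved psychometric refitting and grand average with a circular
#' cluster test; harmonic mixed models (sine/cosine; + alpha; + beta) with
#' the vector-norm permutation test and likelihood-ratio comparisons; the
#' instantaneous-correlation cluster test; the circular lag scan with
#' bootstrap peak-lag CI; optionally the phase-amplitude coupling
#' (modulation index) stage. Every stochastic stage consumes a named
#' substream of the master seed.
#'
#' @param config an [analysis_config()].
#' @return list of class `results_bundle`; written to `config$out_dir` as
#'   JSON + CSV/TSV sidecars when that is set.
#' @export
run_full_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  grid <- phase_bin_grid()
  cohort <- stage("simulate", {
    cfg <- config$simulate
    cfg$seed <- config$seed
    gen_cohort(cfg)
  })
  behav <- stage("behavior", {
    lapply(cohort$participants, function(p) {
      out <- classify_trials(p$trials, config$discard_first)
      out <- out[out$outcome != "excluded", , drop = FALSE]
      data.frame(detected = out$outcome == "hit",
                 contrast = out$contrast, phase = out$phase)
    })
  })
  hit_rates <- vapply(behav, function(d) mean(d$detected), 0)
  mi_gain <- stage("mi_gain", mi_phase_gain_test(behav))
  courses <- stage("refit", {
    lapply(behav, function(d) {
      overall <- fit_psychf(d$contrast, d$detected)
      refit_threshold_by_phase(d$contrast, d$detected, d$phase, overall,
                               grid = grid)
    })
  })
  thresh_z <- course_matrix(courses, "z")
  grand <- grand_average_course(courses)
  course_cluster <- stage("course_cluster", cluster_permutation_test(
    thresh_z, adjacency = "circular", n_perm = config$n_perm_cluster,
    alpha = config$alpha, seed = derive_seed(config$seed, "course_cluster")))
  alpha_mat <- t(vapply(cohort$participants,
                        function(p) p$power_courses[, "alpha"],
                        numeric(grid$n)))
  beta_mat <- if ("beta" %in% colnames(cohort$participants[[1]]$power_courses)) {
    t(vapply(cohort$participants, function(p) p$power_courses[, "beta"],
             numeric(grid$n)))
  } else NULL
  lmem2 <- stage("lmem_base", fit_harmonic_lmem(thresh_z, grid = grid))
  vtest <- stage("vector_norm", permutation_vector_norm_test(
    thresh_z, n_perm = config$n_perm_vector, grid = grid,
    seed = derive_seed(config$seed, "vnorm")))
  lmem4 <- stage("lmem_alpha",
                 fit_harmonic_lmem(thresh_z, alpha_mat, grid = grid))
  lrt24 <- lrt_compare(lmem2, lmem4)
  lmem5 <- lrt45 <- NULL
  if (!is.null(beta_mat)) {
    lmem5 <- stage("lmem_beta", fit_harmonic_lmem(
      thresh_z, list(alpha = alpha_mat, beta = beta_mat), grid = grid))
    lrt45 <- lrt_compare(lmem4, lmem5)
  }
  icorr <- stage("instant_corr", instantaneous_correlation_test(
    alpha_mat, thresh_z, n_perm = config$n_perm_corr, alpha = config$alpha,
    seed = derive_seed(config$seed, "icorr")))
  lagres <- stage("lag_scan", lag_scan(
    alpha_mat, thresh_z, n_null_per_lag = config$n_null_per_lag,
    engine = config$lag_engine, grid = grid,
    seed = derive_seed(config$seed, "lag")))
  boot <- stage("bootstrap", bootstrap_peak_lag(
    alpha_mat, thresh_z, n_boot = config$n_boot, grid = grid,
    seed = derive_seed(config$seed, "boot")))
  pac <- NULL
  if (isTRUE(config$run_pac)) {
    pac <- stage("pac", {
      bands <- vapply(config$simulate$coupling, function(cp) cp$band, "")
      mi_norm <- t(vapply(seq_along(cohort$participants), function(j) {
        sr <- derive_seed(config$seed, sprintf("p%d_run%d", j, 1))
        run_dur <- config$simulate$trials_per_run * config$simulate$iti + 12
        tr <- gen_respiration(config$simulate$respiration, run_dur,
                              config$simulate$fs,
                              seed = derive_seed(sr, "resp"))
        ph <- structure(list(fs = config$simulate$fs,
                             phase = attr(tr, "true_phase"),
                             extrema = list(
                               peak = attr(tr, "true_extrema")$peak,
                               trough = attr(tr, "true_extrema")$trough),
                             valid = rep(TRUE, length(tr$samples))),
                        class = "phase_series")
        env <- do.call(rbind, lapply(seq_along(bands), function(b) {
          gen_coupled_power(ph$phase, config$simulate$coupling[[b]],
                            config$simulate$fs,
                            seed = derive_seed(sr, paste0("pow", b)),
                            coupling_phase =
                              cohort$ground_truth[[j]]$coupling_phase[b]
          )$envelope
        }))
        modulation_index(env, ph, n_surr = config$pac_n_surr,
                         seed = derive_seed(sr, "mi"))$normalized
      }, numeric(length(bands))))
      colnames(mi_norm) <- bands
      gt <- mi_group_test(mi_norm, null_q95 = stats::qnorm(0.95),
                          n_perm = config$n_perm_cluster,
                          alpha = config$alpha,
                          seed = derive_seed(config$seed, "pac_cluster"))
      list(mi_normalized = mi_norm, group_test = gt)
    })
  }
  bundle <- structure(list(
    provenance = list(seed = config$seed, config_hash = config_hash(config),
                      package_version =
                        as.character(utils::packageVersion("respsych"))),
    hit_rates = hit_rates,
    mi_gain = mi_gain,
    grand_average = grand,
    course_cluster = course_cluster,
    lmem_base = lmem2, vector_norm_test = vtest,
    lmem_alpha = lmem4, lrt_alpha = lrt24,
    lmem_beta = lmem5, lrt_beta = lrt45,
    instant_corr = icorr,
    lag_scan = lagres, bootstrap = boot,
    pac = pac,
    thresh_z = thresh_z, alpha_courses = alpha_mat,
    beta_courses = beta_mat),
    class = "results_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Write the results bundle to disk as JSON + TSV sidecars
#'
#' @param bundle a `results_bundle`.
#' @param dir output directory (created if missing).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summarize_lmem <- function(m) {
    if (is.null(m)) return(NULL)
    list(beta = as.list(m$beta), t = as.list(m$t), p = as.list(m$p),
         df = m$df, loglik = m$loglik)
  }
  deg <- function(idx) rad2deg(phase_bin_grid()$centers[idx])
  rec <- list(
    provenance = bundle$provenance,
    hit_rate_mean = mean(bundle$hit_rates),
    mi_gain = list(delta_mean = mean(bundle$mi_gain$delta),
                   z = bundle$mi_gain$test$z, p = bundle$mi_gain$test$p),
    vector_norm = list(v = bundle$vector_norm_test$v,
                       phase_deg = rad2deg(bundle$vector_norm_test$phase),
                       p = bundle$vector_norm_test$p),
    course_cluster = list(
      n_significant = sum(bundle$course_cluster$significant),
      windows_deg = lapply(
        bundle$course_cluster$clusters[bundle$course_cluster$significant],
        function(i) range(deg(i)))),
    lmem_base = summarize_lmem(bundle$lmem_base),
    lmem_alpha = summarize_lmem(bundle$lmem_alpha),
    lrt_alpha = bundle$lrt_alpha,
    lmem_beta = summarize_lmem(bundle$lmem_beta),
    lrt_beta = bundle$lrt_beta,
    instant_corr = list(p = bundle$instant_corr$p,
                        significant = bundle$instant_corr$significant),
    lag = list(peak_lag_deg = bundle$lag_scan$peak_lag_deg,
               ci_deg = bundle$bootstrap$ci_deg))
  write_result_json(rec, file.path(dir, "results.json"))
  write_courses_tsv(t(bundle$thresh_z), file.path(dir, "threshold_z.tsv"))
  write_courses_tsv(t(bundle$alpha_courses), file.path(dir, "alpha_z.tsv"))
  if (!is.null(bundle$beta_courses)) {
    write_courses_tsv(t(bundle$beta_courses), file.path(dir, "beta_z.tsv"))
  }
  invisible(dir)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>\n")
  cat(sprintf("  mean hit rate: %.3f\n", mean(x$hit_rates)))
  cat(sprintf("  MI gain: mean delta %.4f bits, Wilcoxon z = %.2f, p = %.3g\n",
              mean(x$mi_gain$delta), x$mi_gain$test$z, x$mi_gain$test$p))
  cat(sprintf("  vector norm: v = %.4f, p = %.3g\n",
              x$vector_norm_test$v, x$vector_norm_test$p))
  cat(sprintf("  alpha LMEM: t(%d) = %.2f, LRT chi2(%d) = %.2f\n",
              x$lmem_alpha$df, x$lmem_alpha$t["alpha"], x$lrt_alpha$df,
              x$lrt_alpha$chisq))
  cat(sprintf("  peak lag: %+.0f deg, bootstrap CI [%.1f, %.1f] deg\n",
              x$lag_scan$peak_lag_deg, x$bootstrap$ci_deg[1],
              x$bootstrap$ci_deg[2]))
  invisible(x)
}
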