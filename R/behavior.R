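# Behavioral analyses: outcome classification, hit rate, and the
# Gaussian-copula mutual-information (GCMI) model comparison quantifying how
# much respiration phase adds to stimulus contrast in predicting detection.

#' Classify target trials into hits, misses and exclusions
#'
#' The first `discard_first` trials of each run are dropped (staircase
#' burn-in), catch trials are removed, and target trials are labeled:
#' hit = correct-side report, miss = "none" report, excluded = wrong-side
#' report (the hit-rate formula has no slot for wrong-side responses).
#'
#' @param trials TrialTable data.frame with columns `side`, `response`,
#'   and optionally `run` (single run assumed if absent).
#' @param discard_first number of initial trials per run to discard.
#' @return the target-trial subset with an added `outcome` factor
#'   (hit/miss/excluded).
#' @export
classify_trials <- function(trials, discard_first = 20) {
  stopifnot(is.data.frame(trials), discard_first >= 0)
  if (is.null(trials$run)) trials$run <- 1L
  keep <- unlist(lapply(split(seq_len(nrow(trials)), trials$run), function(i) {
    if (discard_first == 0) i
    else if (length(i) > discard_first) i[-seq_len(discard_first)]
    else integer(0)
  }), use.names = FALSE)
  out <- trials[sort(keep), , drop = FALSE]
  out <- out[out$side != "none", , drop = FALSE]
  out$outcome <- ifelse(out$response == out$side, "hit",
                        ifelse(out$response == "none", "miss", "excluded"))
  out$outcome <- factor(out$outcome, levels = c("hit", "miss", "excluded"))
  out
}

#' Hit rate
#'
#' `n_hits / (n_hits + n_misses)`; excluded (wrong-side) trials are ignored.
#'
#' @param outcomes output of [classify_trials()].
#' @return hit rate in \[0, 1\].
#' @export
hit_rate <- function(outcomes) {
  nh <- sum(outcomes$outcome == "hit")
  nm <- sum(outcomes$outcome == "miss")
  if (nh + nm == 0) stop("no hits or misses to compute a hit rate from")
  nh / (nh + nm)
}

#' Copula transform to standard-normal marginals
#'
#' Rank-orders the values (ties get average ranks) and maps rank/(n+1)
#' through the standard-normal quantile function; strictly monotone in the
#' input, so any strictly increasing transform of the input yields identical
#' output.
#'
#' @param values numeric vector, length >= 2.
#' @return vector with (approximately) standard-normal marginal.
#' @export
copula_normalize <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values for the copula transform")
  stats::qnorm(rank(values, ties.method = "average") / (n + 1))
}

# bias-corrected differential entropy (nats) of a Gaussian fit to x (n x d)
gauss_entropy <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < d + 2) stop("too few samples for a ", d, "-dimensional entropy")
  xc <- sweep(x, 2, colMeans(x))
  C <- crossprod(xc) / (n - 1)
  ch <- tryCatch(chol(C), error = function(e) {
    v <- diag(as.matrix(C))
    bad <- which(v <= .Machine$double.eps)
    stop("singular covariance",
         if (length(bad)) paste0(" (feature ", bad[1], " is degenerate)"))
  })
  h <- sum(log(diag(ch))) + 0.5 * d * (log(2 * pi) + 1)
  # small-sample bias correction of E[log det] (psi-function form)
  h - 0.5 * (sum(digamma((n - seq_len(d)) / 2)) + d * log(2 / (n - 1)))
}

#' Gaussian-copula mutual information between a binary label and features
#'
#' `I = H(X) - sum_c p(c) H(X | c)` with Gaussian entropies estimated from
#' class-wise covariances and an analytic small-sample bias correction.
#' Features should be copula-normalized first (see [copula_normalize()]).
#' Near independence the corrected estimate can be slightly negative.
#'
#' @param labels binary vector (logical or two-level).
#' @param features numeric vector or matrix (n x d) of continuous features.
#' @return mutual information in bits.
#' @export
mi_discrete_continuous <- function(labels, features) {
  x <- as.matrix(features)
  y <- as.integer(as.factor(labels))
  stopifnot(nrow(x) == length(y))
  if (length(unique(y)) != 2) stop("both classes must be present")
  if (nrow(x) <= ncol(x) + 2) stop("n must exceed dimension + 2")
  h_all <- gauss_entropy(x)
  h_cond <- 0
  for (c in unique(y)) {
    sel <- y == c
    h_cond <- h_cond + mean(sel) * gauss_entropy(x[sel, , drop = FALSE])
  }
  (h_all - h_cond) / log(2)
}

#' Wilcoxon signed-rank test against zero
#'
#' Exact null distribution for n <= 25 without ties; otherwise the normal
#' approximation with continuity correction (the z statistic is always
#' reported from the normal approximation).
#'
#' @param x numeric vector of differences.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `V` (signed-rank statistic), `z`, `p` (two-sided) and
#'   `n` (non-zero differences).
#' @export
wilcoxon_signed_rank <- function(x, exact_max = 25) {
  x <- x[x != 0]
  n <- length(x)
  if (n < 1) stop("no non-zero differences")
  r <- rank(abs(x))
  V <- sum(r[x > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- 0.5 * sign(V - mu)
  z <- if (sig2 > 0) (V - mu - cc) / sqrt(sig2) else 0
  has_ties <- any(duplicated(abs(x)))
  if (n <= exact_max && !has_ties) {
    p <- min(1, 2 * min(stats::psignrank(V, n),
                        1 - stats::psignrank(V - 1, n)))
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(V = V, z = z, p = p, n = n)
}

#' MI gain from adding respiration phase, with group test
#'
#' Per participant, computes GCMI between detection (hit/miss) and (a)
#' copula-normalized contrast, (b) contrast plus sine and cosine of
#' respiration phase, and tests the per-participant gains against zero with
#' a Wilcoxon signed-rank test. Because the 3-feature estimate carries a
#' different small-sample bias than the 1-feature one, the gain is
#' permutation-bias-corrected per participant: `n_bias_perm` re-computations
#' with shuffled phases estimate the null value of the 3-feature MI, which
#' is subtracted (set `n_bias_perm = 0` for the raw difference).
#'
#' @param participants list of data.frames, one per participant, each with
#'   columns `detected` (logical), `contrast`, `phase` (radians) for the
#'   analyzed (post-discard) target trials.
#' @param n_bias_perm phase permutations per participant for the bias term.
#' @param seed integer seed for the bias permutations.
#' @return list with per-participant `mi_contrast`, `mi_contrast_phase`,
#'   `delta` (bias-corrected gain), and the group `test`
#'   (see [wilcoxon_signed_rank()]).
#' @export
mi_phase_gain_test <- function(participants, n_bias_perm = 20, seed = 1) {
  stopifnot(length(participants) >= 6)
  res <- lapply(seq_along(participants), function(j) {
    d <- participants[[j]]
    stopifnot(all(c("detected", "contrast", "phase") %in% names(d)))
    f1 <- copula_normalize(d$contrast)
    fphase <- cbind(copula_normalize(sin(d$phase)),
                    copula_normalize(cos(d$phase)))
    mi1 <- mi_discrete_continuous(d$detected, f1)
    mi2 <- mi_discrete_continuous(d$detected, cbind(f1, fphase))
    bias <- if (n_bias_perm > 0) {
      with_seed(derive_seed(seed, paste0("mi_bias", j)), {
        mean(vapply(seq_len(n_bias_perm), function(k) {
          idx <- sample.int(nrow(fphase))
          mi_discrete_continuous(d$detected,
                                 cbind(f1, fphase[idx, , drop = FALSE]))
        }, 0))
      })
    } else mi1
    c(mi1 = mi1, mi2 = mi2, bias = bias)
  })
  m <- do.call(rbind, res)
  delta <- m[, "mi2"] - m[, "bias"]
  list(mi_contrast = m[, "mi1"], mi_contrast_phase = m[, "mi2"],
       delta = delta, test = wilcoxon_signed_rank(delta))
}
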