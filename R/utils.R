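# Small shared helpers: circular arithmetic, seed fan-out, z-scoring.

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # %% maps pi -> -pi; keep the +pi representative so peaks/troughs are stable
  w[w == -pi] <- pi
  w
}

#' Circular distance between angles
#'
#' @param a,b angles in radians (recycled).
#' @return absolute circular distance in \[0, pi\].
#' @export
circ_dist <- function(a, b) {
  d <- abs(wrap_angle(a - b))
  pmin(d, 2 * pi - d)
}

#' Circular mean of angles
#'
#' @param x angles in radians.
#' @param w optional non-negative weights.
#' @return mean direction in (-pi, pi].
#' @export
circ_mean <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  atan2(sum(w * sin(x)), sum(w * cos(x)))
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# monotone cumulative phase from a wrapped (-pi, pi] series
unwrap_phase <- function(ph) {
  d <- diff(ph)
  d[d < -pi] <- d[d < -pi] + 2 * pi
  d[d > pi] <- d[d > pi] - 2 * pi
  cumsum(c(ph[1], pmax(d, 0)))
}

# z-score that tolerates zero variance (returns zeros + attribute flag)
zscore_safe <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    out <- rep(0, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (x - mean(x)) / s
}

#' Derive a child seed from a master seed and a stream label
#'
#' Deterministic fan-out of one master seed into named substreams so that
#' pipeline stages draw from isolated, reproducible random streams.
#'
#' @param seed integer master seed.
#' @param label character stream name.
#' @return an integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1, is.finite(seed))
  # polynomial string hash folded into 31 bits, mixed with the master seed
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 2654435) %% 2147483647)
}

# run expr with a local RNG state (restores caller's state afterwards)
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
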