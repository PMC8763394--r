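# Generic cluster-based permutation testing: element-wise dependent-samples
# t statistics, supra-threshold clustering (contiguous runs on a line or a
# circle, rectilinear connectivity on 2-D/3-D grids), cluster-sum masses,
# and a sign-flip max-cluster null for family-wise error control.

# contiguous runs of TRUE, optionally merging across the wrap point
runs_1d <- function(mask, circular = FALSE) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cl <- mapply(function(s, e) s:e, starts[r$values], ends[r$values],
               SIMPLIFY = FALSE)
  if (circular && length(cl) > 1 && mask[1] && mask[length(mask)]) {
    cl[[1]] <- c(cl[[length(cl)]], cl[[1]])
    cl[[length(cl)]] <- NULL
  }
  cl
}

# connected components (rectilinear adjacency) among TRUE cells of a grid
components_grid <- function(mask, dims) {
  cells <- which(mask)
  if (!length(cells)) return(list())
  pos <- match(seq_len(prod(dims)), cells) # element -> cell id or NA
  parent <- seq_along(cells)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  idx <- arrayInd(cells, dims)
  strides <- cumprod(c(1, dims[-length(dims)]))
  for (d in seq_along(dims)) {
    ok <- idx[, d] < dims[d]
    nb <- pos[cells[ok] + strides[d]]
    has <- !is.na(nb)
    a <- which(ok)[has]; b <- nb[has]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(cells), find, 0L)
  split(cells, roots)
}

# clusters and signed masses of a t-map at threshold, for the given tail
cluster_masses <- function(tv, tcrit, tail, adjacency, dims) {
  get_cl <- function(mask) {
    if (adjacency == "grid") components_grid(mask, dims)
    else runs_1d(mask, circular = adjacency == "circular")
  }
  cl <- list(); mass <- numeric(0)
  if (tail %in% c("two", "pos")) {
    cp <- get_cl(tv >= tcrit)
    cl <- c(cl, cp)
    mass <- c(mass, vapply(cp, function(i) sum(tv[i]), 0))
  }
  if (tail %in% c("two", "neg")) {
    cn <- get_cl(tv <= -tcrit)
    cl <- c(cl, cn)
    mass <- c(mass, vapply(cn, function(i) sum(tv[i]), 0))
  }
  list(clusters = cl, mass = mass)
}

#' Cluster-based permutation test of per-participant maps
#'
#' Dependent-samples (one-sample) t statistics per element are thresholded
#' at `cluster_alpha`; supra-threshold elements form clusters by adjacency;
#' the cluster-sum statistic is compared against a max-cluster null obtained
#' by random sign flips of whole participant maps, controlling the
#' family-wise error rate at `alpha`.
#'
#' @param maps numeric matrix participants x elements, or an array with
#'   participants in the first dimension (its remaining dimensions define a
#'   grid).
#' @param adjacency `"linear"` (contiguous runs), `"circular"` (runs that
#'   wrap, for phase-bin courses) or `"grid"` (rectilinear connectivity on
#'   the array dimensions).
#' @param dims grid dimensions when `maps` is a plain matrix but should be
#'   clustered as a grid.
#' @param n_perm number of sign-flip permutations.
#' @param alpha family-wise significance level.
#' @param cluster_alpha element-wise threshold level.
#' @param tail `"two"`, `"pos"` or `"neg"`.
#' @param mu null value tested against.
#' @param seed integer seed.
#' @return object of class `cluster_test_result`: `t` (element-wise map),
#'   `tcrit`, `clusters` (index vectors), `masses`, `p` (per cluster),
#'   `significant` (logical per cluster), `sig_mask` (element-wise), and the
#'   null distribution `null_max`.
#' @export
cluster_permutation_test <- function(maps, adjacency = c("linear", "circular",
                                                         "grid"),
                                     dims = NULL, n_perm = 5000, alpha = 0.05,
                                     cluster_alpha = 0.05,
                                     tail = c("two", "pos", "neg"),
                                     mu = 0, seed = 1) {
  adjacency <- match.arg(adjacency)
  tail <- match.arg(tail)
  if (is.array(maps) && length(dim(maps)) > 2) {
    dims <- dim(maps)[-1]
    maps <- matrix(maps, nrow = dim(maps)[1])
    adjacency <- "grid"
  }
  stopifnot(is.matrix(maps), nrow(maps) >= 2)
  if (adjacency == "grid" && is.null(dims)) dims <- ncol(maps)
  X <- maps - mu
  n <- nrow(X); E <- ncol(X)
  df <- n - 1
  tcrit <- if (tail == "two") stats::qt(1 - cluster_alpha / 2, df)
           else stats::qt(1 - cluster_alpha, df)
  tstat <- function(m, ss) {
    v <- (ss - n * m^2) / (n - 1)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    m / sqrt(v / n)
  }
  ss <- colSums(X^2)
  t_emp <- tstat(colMeans(X), ss)
  emp <- cluster_masses(t_emp, tcrit, tail, adjacency, dims)
  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    M <- crossprod(S, X) / n
    vapply(seq_len(n_perm), function(p) {
      tv <- tstat(M[p, ], ss)
      cm <- cluster_masses(tv, tcrit, tail, adjacency, dims)
      if (length(cm$mass)) max(abs(cm$mass)) else 0
    }, 0)
  })
  pvals <- vapply(emp$mass, function(m) {
    (1 + sum(null_max >= abs(m))) / (n_perm + 1)
  }, 0)
  sig <- pvals <= alpha
  mask <- logical(E)
  for (i in which(sig)) mask[emp$clusters[[i]]] <- TRUE
  structure(list(t = t_emp, tcrit = tcrit, clusters = emp$clusters,
                 masses = emp$mass, p = pvals, significant = sig,
                 sig_mask = mask, null_max = null_max, df = df,
                 tail = tail, adjacency = adjacency, dims = dims),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> %d cluster(s), %d significant (df=%d)\n",
              length(x$clusters), sum(x$significant), x$df))
  if (length(x$clusters)) {
    for (i in seq_along(x$clusters)) {
      cat(sprintf("  cluster %d: %d elements, mass %.2f, p = %.4f%s\n", i,
                  length(x$clusters[[i]]), x$masses[i], x$p[i],
                  if (x$significant[i]) " *" else ""))
    }
  }
  invisible(x)
}
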