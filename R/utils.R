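# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so seeded package functions do not disturb the
#' caller's random number stream. A `NULL` seed leaves the stream alone.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# n sub-seeds derived reproducibly from one master seed (kept < 2^31)
make_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n, replace = FALSE))
}

#' Orthonormal basis of a design's column space
#'
#' Rank-revealing (SVD) basis; singular values below
#' `max(d) * nrow * .Machine$double.eps` are treated as zero.
#' @noRd
ortho_basis <- function(X, tol = NULL) {
  X <- as.matrix(X)
  if (ncol(X) == 0L || nrow(X) == 0L)
    return(list(Q = matrix(0, nrow(X), 0L), rank = 0L))
  s <- svd(X, nv = 0)
  if (is.null(tol)) tol <- max(s$d) * nrow(X) * .Machine$double.eps
  keep <- s$d > tol
  list(Q = s$u[, keep, drop = FALSE], rank = sum(keep))
}

# column-center a matrix within groups defined by a factor (row groups)
center_within <- function(M, idx_by_group) {
  M <- as.matrix(M)
  for (rows in idx_by_group) {
    mu <- colMeans(M[rows, , drop = FALSE])
    M[rows, ] <- sweep(M[rows, , drop = FALSE], 2L, mu)
  }
  M
}

# effective sample size from the initial positive sequence of autocovariances
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 1000L), plot = FALSE,
                   demean = TRUE)$acf[-1]
  s <- 0
  k <- 1L
  while (k + 1L <= length(ac)) {
    pair <- ac[k] + ac[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, n / (1 + 2 * s))
}

# potential scale reduction factor for a list of chains (vectors)
psrf <- function(chains) {
  m <- length(chains)
  n <- min(lengths(chains))
  chains <- lapply(chains, function(x) x[seq_len(n)])
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, stats::var, 0)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
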