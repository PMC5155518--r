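# 1D and 2D genome scans.
#
# Both scans are Henderson-III F-tests. Because every tested random block
# (the locus block {A, AE} in 1D; the pair block {AA, AAE} in 2D) and every
# reduced design decompose into environment-supported columns, all
# projections are direct sums of small per-environment projections:
#   1D reduced  {1, env}                -> per-env span{1}
#   1D full     + {A_i, AE_i.}         -> per-env span{1, x_i}
#   2D reduced  + both loci's blocks   -> per-env span{1, x_i, x_j}
#   2D full     + {AA_ij, AAE_ij.}     -> per-env span{1, x_i, x_j, x_i x_j}
# This makes the exact F computable from per-environment cross products,
# vectorized over all markers (or pairs) and all permutations at once. The
# generic projector route (`henderson_f`) gives identical values and is the
# reference the test suite compares against.

# per-environment scan workspace
scan_prep <- function(geno, pheno) {
  stopifnot(inherits(geno, "qtx_geno"))
  check_pheno_geno(pheno, geno)
  if (anyNA(geno$values))
    stop("genotype matrix contains NA; impute (see code_genotypes missing='mean') before scanning")
  lev <- env_levels(pheno)
  envf <- factor(pheno$environment, levels = lev)
  idx <- split(seq_len(nrow(pheno)), envf)
  ridx <- match(pheno$individual, rownames(geno$values))
  Xobs <- geno$values[ridx, , drop = FALSE]
  m <- ncol(Xobs)
  per_env <- lapply(idx, function(rows) {
    Xh <- Xobs[rows, , drop = FALSE]
    n_h <- length(rows)
    s <- colSums(Xh)
    Xc <- sweep(Xh, 2L, s / n_h)
    ss_c <- colSums(Xc^2)
    list(rows = rows, n = n_h, X = Xh, Xc = Xc, s = s,
         ss_c = ss_c, ok = ss_c > 1e-9 * n_h)
  })
  y <- pheno$value
  yc <- y
  for (pe in per_env) yc[pe$rows] <- y[pe$rows] - mean(y[pe$rows])
  list(env_levels = lev, env = envf, per_env = per_env, m = m,
       markers = colnames(Xobs), n = nrow(pheno), yc = yc,
       mode = geno$mode)
}

# within-environment permutations of the centered response; returns n x P
permute_yc <- function(prep, n_perm) {
  Y <- matrix(prep$yc, prep$n, n_perm)
  for (pe in prep$per_env) {
    block <- vapply(seq_len(n_perm),
                    function(p) prep$yc[pe$rows][sample.int(pe$n)],
                    numeric(pe$n))
    Y[pe$rows, ] <- block
  }
  Y
}

# core 1D statistics for a (possibly multi-column) centered response
# returns list(F = m x P, df_num, df_den) ; untestable entries are NA
scan1d_stats <- function(prep, Yc, joint = TRUE) {
  P <- ncol(Yc)
  H <- length(prep$per_env)
  rss_red <- 0
  if (joint) {
    extra <- matrix(0, prep$m, P)
    df_num <- integer(prep$m)
    for (pe in prep$per_env) {
      cp <- crossprod(pe$Xc, Yc[pe$rows, , drop = FALSE])
      w <- ifelse(pe$ok, 1 / pmax(pe$ss_c, .Machine$double.xmin), 0)
      extra <- extra + cp^2 * w
      df_num <- df_num + pe$ok
      rss_red <- rss_red + sum(Yc[pe$rows, 1L]^2)
    }
  } else {
    cp <- matrix(0, prep$m, P)
    ss <- numeric(prep$m)
    for (pe in prep$per_env) {
      cp <- cp + crossprod(pe$Xc, Yc[pe$rows, , drop = FALSE])
      ss <- ss + pe$ss_c
      rss_red <- rss_red + sum(Yc[pe$rows, 1L]^2)
    }
    ok <- ss > 1e-9 * prep$n
    extra <- cp^2 * ifelse(ok, 1 / pmax(ss, .Machine$double.xmin), 0)
    df_num <- as.integer(ok)
  }
  r_f <- H + df_num
  df_den <- prep$n - r_f
  F <- (extra / df_num) / ((rss_red - extra) / df_den)
  F[df_num == 0L | df_den <= 0L, ] <- NA_real_
  F <- pmax(F, 0)
  list(F = F, df_num = df_num, df_den = df_den)
}

#' One-dimensional genome scan for individual loci
#'
#' For each locus, jointly tests its additive column and its
#' locus-by-environment columns against the environmental means model by a
#' Henderson method III F-test (the joint test is the default; set
#' `joint = FALSE` to test the additive column only). Monomorphic or
#' otherwise degenerate markers are reported as untestable (`F = NA`), not
#' dropped.
#'
#' @param geno a `qtx_geno`.
#' @param pheno a `qtx_pheno`.
#' @param joint test main + environment-interaction columns jointly
#'   (default) or the main column only.
#' @return A data frame of class `qtx_scan1d`: `marker`, `F`, `df_num`,
#'   `df_den`, `p_point` (pointwise F-distribution p), `untestable`.
#' @export
scan_1d <- function(geno, pheno, joint = TRUE) {
  prep <- scan_prep(geno, pheno)
  st <- scan1d_stats(prep, matrix(prep$yc, ncol = 1L), joint = joint)
  F <- st$F[, 1L]
  out <- data.frame(marker = prep$markers, F = F,
                    df_num = st$df_num, df_den = st$df_den,
                    p_point = stats::pf(F, st$df_num, st$df_den,
                                        lower.tail = FALSE),
                    untestable = is.na(F),
                    stringsAsFactors = FALSE)
  structure(out, class = c("qtx_scan1d", "data.frame"),
            joint = joint, n = prep$n, env_levels = prep$env_levels)
}

# core 2D statistics: pairs (i, j) for one anchor i and a set J, vectorized
# over J and permutations. Returns F (|J| x P), df_num, r_red, df_den.
scan2d_stats <- function(prep, i, J, Yc, CPy) {
  P <- ncol(Yc)
  nJ <- length(J)
  extra <- matrix(0, nJ, P)
  rss_red <- matrix(0, nJ, P)
  df_num <- integer(nJ)
  r_red <- integer(nJ)
  for (k in seq_along(prep$per_env)) {
    pe <- prep$per_env[[k]]
    n_h <- pe$n
    xi <- pe$X[, i]
    xi2 <- xi^2
    Yh <- Yc[pe$rows, , drop = FALSE]
    ynorm <- sum(Yh[, 1L]^2)

    p1 <- as.vector(crossprod(pe$X, xi))[J]          # p'1   = sum x_i x_j
    pxi <- as.vector(crossprod(pe$X, xi2))[J]        # p'x_i = sum x_i^2 x_j
    pxj <- as.vector(crossprod(pe$X^2, xi))[J]       # p'x_j = sum x_i x_j^2
    pp <- as.vector(crossprod(pe$X^2, xi2))[J]       # p'p
    g <- as.vector(crossprod(pe$Xc, pe$Xc[, i]))[J]  # centered x_i'x_j
    si <- pe$s[i]
    sj <- pe$s[J]
    ssi <- pe$ss_c[i]
    ssj <- pe$ss_c[J]

    B <- pxi - p1 * si / n_h      # centered p'x_i
    C <- pxj - p1 * sj / n_h      # centered p'x_j
    ppc <- pmax(pp - p1^2 / n_h, 0)

    D <- CPy[[k]][i, ]                       # P-vector
    E <- CPy[[k]][J, , drop = FALSE]         # nJ x P

    oki <- isTRUE(pe$ok[i])
    okj <- pe$ok[J]
    det <- ssi * ssj - g^2
    full2 <- oki & okj & det > 1e-9 * ssi * ssj

    fit <- matrix(0, nJ, P)
    rr <- ppc
    ry <- matrix(0, nJ, P)
    rnk <- integer(nJ)

    if (any(full2)) {
      jj <- which(full2)
      al <- (B[jj] * ssj[jj] - C[jj] * g[jj]) / det[jj]
      be <- (C[jj] * ssi - B[jj] * g[jj]) / det[jj]
      fit[jj, ] <- (outer(ssj[jj], D^2) -
                      2 * g[jj] * E[jj, , drop = FALSE] *
                      rep(D, each = length(jj)) +
                      E[jj, , drop = FALSE]^2 * ssi) / det[jj]
      rr[jj] <- pmax(ppc[jj] - al * B[jj] - be * C[jj], 0)
      ry[jj, ] <- -outer(al, D) - be * E[jj, , drop = FALSE]
      rnk[jj] <- 2L
    }
    r1i <- !full2 & oki                       # project on x_i only
    if (any(r1i)) {
      jj <- which(r1i)
      co <- B[jj] / ssi
      fit[jj, ] <- matrix(D^2 / ssi, length(jj), P, byrow = TRUE)
      rr[jj] <- pmax(ppc[jj] - B[jj]^2 / ssi, 0)
      ry[jj, ] <- -outer(co, D)
      rnk[jj] <- 1L
    }
    r1j <- !full2 & !oki & okj                # project on x_j only
    if (any(r1j)) {
      jj <- which(r1j)
      co <- C[jj] / ssj[jj]
      fit[jj, ] <- E[jj, , drop = FALSE]^2 / ssj[jj]
      rr[jj] <- pmax(ppc[jj] - C[jj]^2 / ssj[jj], 0)
      ry[jj, ] <- -co * E[jj, , drop = FALSE]
      rnk[jj] <- 1L
    }
    # residual product-column response cross products
    py <- crossprod(pe$X, xi * Yh)[J, , drop = FALSE]  # centered-y p'y
    ry <- ry + py
    okp <- rr > pmax(1e-9 * ppc, 1e-12)
    w <- ifelse(okp, 1 / pmax(rr, .Machine$double.xmin), 0)
    extra <- extra + ry^2 * w
    rss_red <- rss_red + (ynorm - fit)
    df_num <- df_num + okp
    r_red <- r_red + 1L + rnk
  }
  df_den <- prep$n - r_red - df_num
  F <- (extra / df_num) / ((rss_red - extra) / df_den)
  F[df_num == 0L | df_den <= 0L, ] <- NA_real_
  F <- pmax(F, 0)
  list(F = F, df_num = df_num, df_den = df_den)
}

# cross products of centered genotypes with (possibly permuted) responses,
# one m x P matrix per environment; shared by 1D and 2D cores
scan_cpy <- function(prep, Yc) {
  lapply(prep$per_env, function(pe)
    crossprod(pe$Xc, Yc[pe$rows, , drop = FALSE]))
}

# canonical pair enumeration for a scope
pair_index_set <- function(m, selected_idx = NULL,
                           scope = c("all", "selected")) {
  scope <- match.arg(scope)
  if (scope == "all") {
    anchors <- seq_len(max(m - 1L, 0L))
    lapply(anchors, function(i) list(i = i, J = seq.int(i + 1L, m)))
  } else {
    if (is.null(selected_idx) || length(selected_idx) == 0L) return(list())
    selected_idx <- sort(unique(selected_idx))
    out <- list()
    seen_anchor <- integer(0)
    for (i in selected_idx) {
      J <- setdiff(seq_len(m), i)
      # drop pairs already enumerated from an earlier selected anchor
      J <- J[!(J %in% seen_anchor)]
      if (length(J)) out[[length(out) + 1L]] <- list(i = i, J = J)
      seen_anchor <- c(seen_anchor, i)
    }
    out
  }
}

#' Two-dimensional scan for epistatic pairs
#'
#' For each marker pair, tests the epistasis block (the product column and
#' its environment interactions) against a reduced model that contains the
#' intercept, the environments, and *both* loci's main and
#' locus-by-environment columns, so the F-statistic isolates
#' additive-by-additive epistasis. The scan is exhaustive over all
#' `m(m-1)/2` pairs (`scope = "all"`) or restricted to pairs involving the
#' loci already declared significant in the 1D step
#' (`scope = "selected"`).
#'
#' @param geno a `qtx_geno`.
#' @param pheno a `qtx_pheno`.
#' @param selected marker ids from the 1D step (required for
#'   `scope = "selected"`).
#' @param scope `"all"` or `"selected"`.
#' @return A data frame of class `qtx_scan2d`: `marker_i`, `marker_j`
#'   (canonical order), `F`, `df_num`, `df_den`, `p_point`, `untestable`.
#' @export
scan_2d <- function(geno, pheno, selected = NULL,
                    scope = c("all", "selected")) {
  scope <- match.arg(scope)
  prep <- scan_prep(geno, pheno)
  sel_idx <- if (!is.null(selected)) match(selected, prep$markers) else NULL
  if (!is.null(sel_idx) && anyNA(sel_idx))
    stop("unknown selected marker: ", selected[is.na(sel_idx)][1L])
  sets <- pair_index_set(prep$m, sel_idx, scope)
  Yc <- matrix(prep$yc, ncol = 1L)
  CPy <- scan_cpy(prep, Yc)
  rows <- lapply(sets, function(sp) {
    st <- scan2d_stats(prep, sp$i, sp$J, Yc, CPy)
    data.frame(i = pmin(sp$i, sp$J), j = pmax(sp$i, sp$J),
               F = st$F[, 1L], df_num = st$df_num, df_den = st$df_den,
               stringsAsFactors = FALSE)
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(0), j = integer(0), F = numeric(0),
               df_num = integer(0), df_den = integer(0))
  res <- res[order(res$i, res$j), , drop = FALSE]
  out <- data.frame(marker_i = prep$markers[res$i],
                    marker_j = prep$markers[res$j],
                    F = res$F, df_num = res$df_num, df_den = res$df_den,
                    p_point = stats::pf(res$F, res$df_num, res$df_den,
                                        lower.tail = FALSE),
                    untestable = is.na(res$F),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("qtx_scan2d", "data.frame"),
            scope = scope, n = prep$n, env_levels = prep$env_levels)
}

#' Permutation threshold for the experiment-wise error rate
#'
#' Estimates the critical F controlling the experiment-wise type I error of
#' a whole scan by the max-statistic permutation null: phenotype records
#' are shuffled across individuals *within each environment* (one shared
#' permutation per replicate for all tests), the full scan is re-run, and
#' the maximum F recorded. The critical value is the conservative "higher"
#' empirical quantile: the smallest null maximum whose exceedance
#' proportion is at most `alpha` (for `alpha = 0.05`, `n_perm = 2000`, the
#' 100th largest null maximum).
#'
#' @param geno,pheno data as in the scans.
#' @param scope `"1d"` (locus scan) or `"2d"` (pair scan).
#' @param alpha experiment-wise error rate.
#' @param n_perm number of permutations (2000 by default; a warning is
#'   given when `n_perm < 1/alpha`).
#' @param seed integer seed; the null is bit-reproducible given the seed.
#' @param selected,pair_scope passed to [scan_2d()] when `scope = "2d"`.
#' @param joint passed to [scan_1d()] when `scope = "1d"`.
#' @return An object of class `qtx_threshold`: list with `alpha`,
#'   `n_perm`, `max_F_null`, `critical_F`, `seed`, `scope`.
#' @export
permutation_threshold <- function(geno, pheno, scope = c("1d", "2d"),
                                  alpha = 0.05, n_perm = 2000L, seed = 1L,
                                  selected = NULL,
                                  pair_scope = c("selected", "all"),
                                  joint = TRUE) {
  scope <- match.arg(scope)
  pair_scope <- match.arg(pair_scope)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (n_perm < 1 / alpha)
    warning(sprintf("n_perm = %d is below 1/alpha = %.0f; the threshold is coarse",
                    n_perm, 1 / alpha))
  prep <- scan_prep(geno, pheno)
  Yp <- with_seed(seed, permute_yc(prep, n_perm))
  if (scope == "1d") {
    st <- scan1d_stats(prep, Yp, joint = joint)
    maxF <- apply(st$F, 2L, max, na.rm = TRUE)
  } else {
    sel_idx <- if (!is.null(selected)) match(selected, prep$markers) else NULL
    if (!is.null(sel_idx) && anyNA(sel_idx))
      stop("unknown selected marker: ", selected[is.na(sel_idx)][1L])
    sets <- pair_index_set(prep$m, sel_idx, pair_scope)
    if (length(sets) == 0L) stop("2d permutation threshold: no pairs in scope")
    CPy <- scan_cpy(prep, Yp)
    maxF <- rep(-Inf, n_perm)
    for (sp in sets) {
      st <- scan2d_stats(prep, sp$i, sp$J, Yp, CPy)
      mx <- suppressWarnings(apply(st$F, 2L, max, na.rm = TRUE))
      maxF <- pmax(maxF, mx, na.rm = TRUE)
    }
  }
  maxF[!is.finite(maxF)] <- 0
  k <- max(1L, floor(alpha * n_perm))
  crit <- if (alpha >= 1) 0 else sort(maxF, decreasing = TRUE)[min(k, n_perm)]
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 max_F_null = maxF, critical_F = crit,
                 seed = as.integer(seed), scope = scope),
            class = "qtx_threshold")
}

#' @export
print.qtx_threshold <- function(x, ...) {
  cat(sprintf("qtx_threshold (%s): critical F = %.3f (alpha = %g, %d permutations, seed %d)\n",
              x$scope, x$critical_F, x$alpha, x$n_perm, x$seed))
  invisible(x)
}

#' Peaks of a 1D F-statistic profile
#'
#' A peak is a marker whose F strictly exceeds both chromosome neighbours
#' (chromosome ends are compared to their single neighbour); on a plateau
#' of tied F values the marker at the lower map position takes the peak.
#' Untestable markers never peak. Without a map the profile is treated as
#' one chromosome in scan order.
#'
#' @param scan1d result of [scan_1d()].
#' @param map optional `qtx_map`.
#' @param critical_F only peaks with `F >= critical_F` are returned
#'   (default `-Inf`: all local maxima).
#' @return character vector of peak marker ids, in decreasing F order.
#' @export
find_peaks <- function(scan1d, map = NULL, critical_F = -Inf) {
  F <- scan1d$F
  names(F) <- scan1d$marker
  if (!is.null(map)) {
    keep <- map$marker[map$marker %in% scan1d$marker]
    chrom <- map$chrom[match(keep, map$marker)]
    F <- F[keep]
  } else {
    chrom <- rep("1", length(F))
  }
  F0 <- ifelse(is.na(F), -Inf, F)
  peaks <- character(0)
  for (ch in unique(chrom)) {
    f <- F0[chrom == ch]
    if (length(f) == 1L) {
      if (is.finite(f)) peaks <- c(peaks, names(f))
      next
    }
    left <- c(-Inf, f[-length(f)])
    right <- c(f[-1L], -Inf)
    is_pk <- f > left & f >= right & is.finite(f)
    peaks <- c(peaks, names(f)[is_pk])
  }
  peaks <- peaks[F0[peaks] >= critical_F]
  peaks[order(F0[peaks], decreasing = TRUE)]
}
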