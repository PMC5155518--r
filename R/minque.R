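# MINQUE(1) variance components and AUP effect prediction.

# Q matrix of MINQUE with prior values 1:
#   V1 = sum_v U_v U_v' + I,  Q = V1^-1 - V1^-1 X (X'V1^-1 X)^+ X' V1^-1
# computed with the Woodbury identity so the O(n^2) work is a few thin
# matrix products.
minque_q <- function(X, blocks, kinship = NULL) {
  n <- nrow(X)
  U <- lapply(names(blocks), function(v) {
    Uv <- blocks[[v]]
    K <- kinship[[v]] %||% NULL
    if (!is.null(K)) {
      R <- chol(K + diag(1e-10, ncol(Uv)))
      Uv <- Uv %*% t(R)    # V_v = U K U' = (U R') (U R')'
    }
    Uv
  })
  names(U) <- names(blocks)
  Uall <- do.call(cbind, U)
  q <- ncol(Uall) %||% 0L
  if (is.null(Uall) || q == 0L) {
    M <- diag(n)
  } else {
    W <- solve(diag(q) + crossprod(Uall))
    M <- diag(n) - Uall %*% W %*% t(Uall)   # V1^-1
  }
  A <- M %*% X
  S <- tryCatch(solve(crossprod(X, A)),
                error = function(e) MASS_ginv(crossprod(X, A)))
  Q <- M - A %*% S %*% t(A)
  list(Q = Q, U = U)
}

# small Moore-Penrose pseudoinverse (symmetric use)
MASS_ginv <- function(M, tol = sqrt(.Machine$double.eps)) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' MINQUE(1) estimation of variance components
#'
#' Estimates one variance component per random-effect class (`A`, `AA`,
#' `AE`, `AAE`) plus the residual by Minimum Norm Quadratic Unbiased
#' Estimation with all prior values set to 1: with
#' `V_v = U_v K_v U_v'`, `V1 = sum_v V_v + I` and
#' `Q = V1^-1 - V1^-1 X (X'V1^-1 X)^+ X'V1^-1`, it solves the trace system
#' \deqn{\sum_u tr(Q V_u Q V_v)\,\sigma^2_u = y' Q V_v Q y}
#' over all classes `v`. Negative solutions are truncated to zero after
#' solving (the untruncated values are kept in `sigma2_raw`; truncation
#' after solving preserves the estimator's unbiasedness). Heritability of a
#' class is its component divided by the phenotypic variance (the sum of
#' all components).
#'
#' @param design a `qtx_design` with at least one random block.
#' @param y response vector (defaults to the design's phenotype).
#' @return An object of class `qtx_vc`: list with `sigma2` (named,
#'   truncated), `sigma2_raw`, `truncated` (logical), `phenotypic_variance`,
#'   `heritability`, and the internals (`Q`, transformed `U`) reused by
#'   [aup_predict()].
#' @export
minque1 <- function(design, y = design$y) {
  stopifnot(inherits(design, "qtx_design"))
  if (length(design$blocks) == 0L)
    stop("minque1 needs at least one random block")
  if (length(y) != nrow(design$X)) stop("dimension mismatch: y vs design")
  qd <- minque_q(design$X, design$blocks, design$kinship)
  Q <- qd$Q
  U <- qd$U
  classes <- c(names(U), "residual")
  nc <- length(classes)
  QU <- lapply(U, function(Uv) Q %*% Uv)
  Qy <- Q %*% y
  T <- matrix(0, nc, nc, dimnames = list(classes, classes))
  rhs <- numeric(nc)
  for (a in seq_along(U)) {
    for (b in seq_len(a)) {
      val <- sum(crossprod(U[[a]], QU[[b]])^2)
      T[a, b] <- T[b, a] <- val
    }
    T[a, nc] <- T[nc, a] <- sum(QU[[a]]^2)
    rhs[a] <- sum(crossprod(U[[a]], Qy)^2)
  }
  T[nc, nc] <- sum(Q^2)
  rhs[nc] <- sum(Qy^2)
  if (rcond(T) < .Machine$double.eps * 100) {
    stop("MINQUE trace system is singular; collinear random blocks: ",
         paste(classes[-nc], collapse = ", "))
  }
  sol <- solve(T, rhs)
  names(sol) <- classes
  sigma2 <- pmax(sol, 0)
  vp <- sum(sigma2)
  structure(list(sigma2 = sigma2, sigma2_raw = sol,
                 truncated = sol < 0,
                 phenotypic_variance = vp,
                 heritability = if (vp > 0) sigma2 / vp else sigma2 * 0,
                 Q = Q, U = U, classes = classes),
            class = "qtx_vc")
}

#' @export
print.qtx_vc <- function(x, ...) {
  df <- data.frame(sigma2 = x$sigma2, h2 = x$heritability)
  cat("MINQUE(1) variance components:\n")
  print(df, ...)
  invisible(x)
}

#' Adjusted Unbiased Prediction (AUP) of individual random effects
#'
#' Predicts the individual effects in each random class from the linear
#' score `U_v' Q y`, rescaled so that the sample variance of the predicted
#' effects in class `v` reproduces the class's MINQUE(1) component exactly:
#' `e_hat_v = kappa_v U_v' Q y` with
#' `kappa_v = sqrt(q_v sigma2_v / ||U_v'Qy||^2)`. Classes with a zero
#' component get all-zero predictions. Standard errors, when requested,
#' come from a delete-one-individual jackknife (grouping by individual id;
#' `jackknife_groups` merges individuals into that many blocks for a
#' faster grouped jackknife).
#'
#' @param design a `qtx_design`.
#' @param y response vector.
#' @param vc the [minque1()] fit on the same design and response.
#' @param se `"none"` or `"jackknife"`.
#' @param jackknife_groups optional number of jackknife blocks.
#' @return An object of class `qtx_effects`: data frame with `term`,
#'   `class`, `locus1`, `locus2`, `environment`, `estimate`, `se`, `p`.
#' @export
aup_predict <- function(design, y = design$y, vc,
                        se = c("none", "jackknife"),
                        jackknife_groups = NULL) {
  se <- match.arg(se)
  est <- aup_point(design, y, vc)
  out <- est$table
  if (se == "jackknife") {
    ids <- unique(design$individuals)
    groups <- if (is.null(jackknife_groups)) as.list(ids) else
      split(ids, cut(seq_along(ids), breaks = jackknife_groups,
                     labels = FALSE))
    g <- length(groups)
    reps <- matrix(NA_real_, g, nrow(out))
    for (k in seq_len(g)) {
      keep <- !(design$individuals %in% groups[[k]])
      dk <- subset_design(design, keep)
      vck <- minque1(dk, y[keep])
      reps[k, ] <- aup_point(dk, y[keep], vck)$table$estimate
    }
    bar <- colMeans(reps)
    out$se <- sqrt((g - 1) / g * colSums(sweep(reps, 2L, bar)^2))
    z <- out$estimate / out$se
    out$p <- 2 * stats::pnorm(-abs(z))
  }
  structure(out, class = c("qtx_effects", "data.frame"))
}

# point predictions only (no SE); shared by aup_predict and the jackknife
aup_point <- function(design, y, vc) {
  stopifnot(inherits(vc, "qtx_vc"))
  Qy <- vc$Q %*% y
  rows <- list()
  for (v in names(vc$U)) {
    tv <- as.vector(crossprod(vc$U[[v]], Qy))
    qv <- length(tv)
    s2 <- vc$sigma2[[v]]
    if (s2 > 0) {
      nrm <- sum(tv^2)
      if (nrm <= 0)
        stop("degenerate geometry: zero score with positive variance in class ", v)
      ev <- sqrt(qv * s2 / nrm) * tv
    } else ev <- rep(0, qv)
    tb <- design$terms[[v]]
    tb$term <- colnames(design$blocks[[v]])
    tb$estimate <- ev
    rows[[v]] <- tb
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$se <- NA_real_
  tab$p <- NA_real_
  tab <- tab[, c("term", "class", "locus1", "locus2", "environment",
                 "estimate", "se", "p")]
  list(table = tab)
}

#' Heritability report
#'
#' Per-class heritabilities from the variance components, the residual
#' proportion, and a descriptive per-locus decomposition
#' `h2_i = a_i^2 Var(x_i) / Vp` from the AUP additive effects.
#'
#' @param vc a `qtx_vc`.
#' @param effects a `qtx_effects` from [aup_predict()].
#' @param design the `qtx_design` both were fitted on.
#' @return data frame with columns `component`, `class`, `h2`.
#' @export
heritability_report <- function(vc, effects, design) {
  vp <- vc$phenotypic_variance
  out <- data.frame(component = names(vc$heritability),
                    class = names(vc$heritability),
                    h2 = as.numeric(vc$heritability),
                    stringsAsFactors = FALSE)
  add <- effects[effects$class == "A", , drop = FALSE]
  if (nrow(add) && vp > 0) {
    vx <- apply(design$blocks$A, 2L, stats::var)
    out <- rbind(out,
                 data.frame(component = paste0("locus:", add$locus1),
                            class = "A_locus",
                            h2 = add$estimate^2 * vx / vp,
                            stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
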