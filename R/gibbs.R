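# Gibbs sampling of the mixed model equations for the final model.

#' Gibbs-sampling estimation of effects and variance components
#'
#' Samples the joint posterior of the mixed linear model by a full
#' conditional sweep per cycle: (1) fixed effects from their normal full
#' conditional (flat prior); (2) each random-effect block `e_v` from its
#' normal full conditional with shrinkage `lambda_v = sigma2_e / sigma2_v`;
#' (3) each variance from its scaled inverse-chi-square full conditional.
#' Priors on variances are scaled inverse-chi-square with `nu0 = 4` and
#' scale set from a MINQUE(1) fit when supplied (weakly informative
#' fallback: `0.1 * var(y)`). Variances are floored at `1e-12 * var(y)` to
#' keep the conditionals proper. The chain is deterministic given `seed`.
#'
#' @param design a `qtx_design` (as assembled by [stepwise_select()] +
#'   [build_design()]).
#' @param y response vector.
#' @param chain_length total Gibbs cycles (default 200000).
#' @param thin keep every `thin`-th post-burn-in cycle (default 10).
#' @param burn_in cycles discarded before retention (default 20000).
#' @param seed integer seed.
#' @param vc optional [minque1()] fit used to centre the variance priors.
#' @param nu0 prior degrees of freedom for every variance (default 4).
#' @param keep_samples return the thinned samples matrix.
#' @return An object of class `qtx_posterior`: data frame `summary` with
#'   posterior mean, SD, central 95% interval, effective sample size and
#'   Monte-Carlo SE per parameter, plus the configuration (and `samples`
#'   when requested).
#' @export
gibbs_estimate <- function(design, y = design$y, chain_length = 200000L,
                           thin = 10L, burn_in = 20000L, seed = 1L,
                           vc = NULL, nu0 = 4, keep_samples = FALSE) {
  stopifnot(inherits(design, "qtx_design"))
  if (burn_in >= chain_length) stop("burn_in must be below chain_length")
  if (thin < 1L) stop("thinning interval must be >= 1")
  X <- design$X
  n <- nrow(X)
  p <- ncol(X)
  blocks <- design$blocks
  vnames <- names(blocks)
  qv <- vapply(blocks, ncol, 0L)
  vy <- stats::var(y)
  floor_v <- 1e-12 * vy

  s0 <- stats::setNames(rep(0.1 * vy, length(vnames) + 1L),
                        c(vnames, "residual"))
  if (!is.null(vc)) {
    for (v in names(s0))
      if (v %in% names(vc$sigma2) && vc$sigma2[[v]] > floor_v)
        s0[v] <- vc$sigma2[[v]]
  }

  XtX <- crossprod(X)
  Rx <- chol(XtX)
  G <- lapply(blocks, crossprod)              # U_v'U_v
  UtX <- lapply(blocks, function(U) crossprod(U, X))

  n_keep <- floor((chain_length - burn_in) / thin)
  pn <- c(colnames(X) %||% paste0("b", seq_len(p)),
          unlist(lapply(vnames, function(v) colnames(blocks[[v]]))),
          paste0("sigma2_", c(vnames, "residual")))
  samples <- matrix(NA_real_, n_keep, length(pn),
                    dimnames = list(NULL, pn))

  with_seed(seed, {
    b <- backsolve(Rx, backsolve(Rx, crossprod(X, y), transpose = TRUE))
    e <- lapply(qv, function(q) numeric(q))
    s2 <- s0
    s2e <- s0[["residual"]]
    r <- y - X %*% b
    for (v in vnames) r <- r - blocks[[v]] %*% e[[v]]
    r <- as.vector(r)
    keep_i <- 0L
    for (it in seq_len(chain_length)) {
      # fixed effects
      r_b <- r + as.vector(X %*% b)
      mu_b <- backsolve(Rx, backsolve(Rx, crossprod(X, r_b), transpose = TRUE))
      b <- as.vector(mu_b + sqrt(s2e) * backsolve(Rx, stats::rnorm(p)))
      r <- r_b - as.vector(X %*% b)
      # random blocks
      for (v in vnames) {
        Uv <- blocks[[v]]
        r_v <- r + as.vector(Uv %*% e[[v]])
        C <- G[[v]] / s2e + diag(1 / s2[[v]], qv[[v]])
        Rc <- chol(C)
        mu <- backsolve(Rc, backsolve(Rc, crossprod(Uv, r_v) / s2e,
                                      transpose = TRUE))
        e[[v]] <- as.vector(mu + backsolve(Rc, stats::rnorm(qv[[v]])))
        r <- r_v - as.vector(Uv %*% e[[v]])
        s2[[v]] <- max((nu0 * s0[[v]] + sum(e[[v]]^2)) /
                         stats::rchisq(1L, nu0 + qv[[v]]), floor_v)
      }
      s2e <- max((nu0 * s0[["residual"]] + sum(r^2)) /
                   stats::rchisq(1L, nu0 + n), floor_v)
      if (it > burn_in && (it - burn_in) %% thin == 0L) {
        keep_i <- keep_i + 1L
        samples[keep_i, ] <- c(b, unlist(e),
                               unname(c(s2[vnames], residual = s2e)))
      }
    }
  })
  samples <- samples[seq_len(keep_i), , drop = FALSE]
  qs <- apply(samples, 2L, stats::quantile, probs = c(0.025, 0.975))
  ness <- apply(samples, 2L, ess)
  sds <- apply(samples, 2L, stats::sd)
  summ <- data.frame(parameter = colnames(samples),
                     mean = colMeans(samples),
                     sd = sds,
                     q2.5 = qs[1L, ], q97.5 = qs[2L, ],
                     ess = ness,
                     mcse = sds / sqrt(ness),
                     stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  structure(list(summary = summ,
                 samples = if (keep_samples) samples else NULL,
                 chain_length = chain_length, thin = thin,
                 burn_in = burn_in, seed = seed),
            class = "qtx_posterior")
}

#' @export
print.qtx_posterior <- function(x, ...) {
  cat(sprintf("qtx_posterior: %d retained samples (chain %d, thin %d, burn-in %d)\n",
              nrow(x$summary) * 0 + (x$chain_length - x$burn_in) %/% x$thin,
              x$chain_length, x$thin, x$burn_in))
  print(utils::head(x$summary, 12), ...)
  invisible(x)
}
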