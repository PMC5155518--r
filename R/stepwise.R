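# Stepwise assembly of the final candidate model from significant peaks.

# design columns contributed by one term (locus or pair): the main column
# plus its environment-interaction columns
term_columns <- function(geno, pheno, term) {
  lev <- env_levels(pheno)
  envf <- factor(pheno$environment, levels = lev)
  ridx <- match(pheno$individual, rownames(geno$values))
  x <- if (length(term) == 1L) geno$values[ridx, term] else
    geno$values[ridx, term[1L]] * geno$values[ridx, term[2L]]
  cols <- matrix(x, ncol = 1L)
  if (length(lev) > 1L)
    cols <- cbind(cols, vapply(lev, function(h) x * (envf == h),
                               numeric(length(x))))
  cols
}

#' Stepwise selection of candidate loci and epistatic pairs
#'
#' Assembles the final candidate set from the significant peaks of the 1D
#' profile and the significant pairs of the 2D profile: candidates enter in
#' decreasing F order if their *conditional* Henderson-III F (given all
#' terms already in the model) still clears the corresponding permutation
#' threshold; after each forward sweep, included terms whose conditional F
#' has fallen below the threshold are dropped (worst first); forward and
#' backward sweeps alternate to a fixed point. The procedure is
#' deterministic.
#'
#' @param geno,pheno data as in the scans.
#' @param scan1d,threshold1d 1D profile ([scan_1d()]) and its
#'   [permutation_threshold()].
#' @param scan2d,threshold2d optional 2D profile and threshold.
#' @param map optional `qtx_map` used for peak finding.
#' @param max_iter safety cap on forward/backward alternations.
#' @return An object of class `qtx_candidates`: list with data frames
#'   `loci` (`marker`, `F_cond`) and `pairs` (`marker_i`, `marker_j`,
#'   `F_cond`), plus the thresholds used.
#' @export
stepwise_select <- function(geno, pheno, scan1d, threshold1d,
                            scan2d = NULL, threshold2d = NULL,
                            map = NULL, max_iter = 25L) {
  crit1 <- threshold1d$critical_F
  peaks <- find_peaks(scan1d, map, crit1)
  cand <- lapply(peaks, function(mk)
    list(type = "locus", id = mk,
         F = scan1d$F[match(mk, scan1d$marker)]))
  if (!is.null(scan2d) && nrow(scan2d)) {
    crit2 <- threshold2d$critical_F
    sig <- which(!scan2d$untestable & scan2d$F >= crit2)
    cand <- c(cand, lapply(sig, function(r)
      list(type = "pair", id = c(scan2d$marker_i[r], scan2d$marker_j[r]),
           F = scan2d$F[r])))
  } else crit2 <- NA_real_

  if (length(cand) == 0L)
    return(structure(list(loci = data.frame(marker = character(0),
                                            F_cond = numeric(0)),
                          pairs = data.frame(marker_i = character(0),
                                             marker_j = character(0),
                                             F_cond = numeric(0)),
                          critical_F_1d = crit1, critical_F_2d = crit2),
                     class = "qtx_candidates"))

  cand <- cand[order(vapply(cand, `[[`, 0, "F"), decreasing = TRUE)]
  lev <- env_levels(pheno)
  X <- build_design(geno, pheno)$X
  y <- pheno$value
  cols <- lapply(cand, function(cn) term_columns(geno, pheno, cn$id))
  crit_of <- function(cn) if (cn$type == "locus") crit1 else crit2

  included <- logical(length(cand))
  cond_F <- rep(NA_real_, length(cand))
  changed <- TRUE
  iter <- 0L
  while (changed && iter < max_iter) {
    changed <- FALSE
    iter <- iter + 1L
    # forward sweep
    for (k in seq_along(cand)) {
      if (included[k]) next
      base <- do.call(cbind, c(list(X), cols[included]))
      f <- henderson_f(y, cbind(base, cols[[k]]), base)
      if (!f$untestable && f$F >= crit_of(cand[[k]])) {
        included[k] <- TRUE
        changed <- TRUE
      }
    }
    # backward sweep: drop the weakest failing term, recompute, repeat
    repeat {
      idx <- which(included)
      if (length(idx) == 0L) break
      ratios <- vapply(idx, function(k) {
        others <- setdiff(idx, k)
        base <- do.call(cbind, c(list(X), cols[others]))
        f <- henderson_f(y, cbind(base, cols[[k]]), base)
        cond_F[k] <<- if (f$untestable) NA_real_ else f$F
        if (f$untestable) -Inf else f$F / crit_of(cand[[k]])
      }, 0)
      if (all(ratios >= 1, na.rm = FALSE) && !anyNA(ratios)) break
      worst <- idx[which.min(ratios)]
      included[worst] <- FALSE
      changed <- TRUE
    }
  }

  idx <- which(included)
  types <- vapply(cand[idx], `[[`, "", "type")
  loci <- vapply(cand[idx[types == "locus"]], `[[`, "", "id")
  lF <- cond_F[idx[types == "locus"]]
  pr <- cand[idx[types == "pair"]]
  structure(list(
    loci = data.frame(marker = as.character(loci), F_cond = lF,
                      stringsAsFactors = FALSE),
    pairs = data.frame(
      marker_i = vapply(pr, function(cn) cn$id[1L], ""),
      marker_j = vapply(pr, function(cn) cn$id[2L], ""),
      F_cond = cond_F[idx[types == "pair"]],
      stringsAsFactors = FALSE),
    critical_F_1d = crit1, critical_F_2d = crit2),
    class = "qtx_candidates")
}

#' @export
print.qtx_candidates <- function(x, ...) {
  cat(sprintf("qtx_candidates: %d loci, %d pairs (critical F: 1d %.3f%s)\n",
              nrow(x$loci), nrow(x$pairs), x$critical_F_1d,
              if (is.na(x$critical_F_2d)) "" else
                sprintf(", 2d %.3f", x$critical_F_2d)))
  invisible(x)
}
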