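# Replicated simulate -> scan -> select experiments: detection power and
# effect-estimate summaries for the planted architecture.

#' Power and unbiasedness experiment
#'
#' Repeats the full detection pipeline on freshly simulated data: genotype
#' and phenotype simulation, 1D scan with its permutation threshold, 2D
#' scan over pairs involving the 1D-significant peaks (or all pairs) with
#' its own permutation threshold, and stepwise selection. A planted locus
#' counts as detected in a replicate when a retained marker is the locus
#' itself or within `window` markers of it on the same chromosome
#' (default: the exact marker); a planted pair counts when both members of
#' a retained pair match this way. Power is the percentage of replicates
#' detecting the term. With `estimate_effects = TRUE`, MINQUE(1)/AUP runs
#' on the selected model in every replicate and the mean and SE of the
#' estimates for the planted terms are reported.
#'
#' @param config a `qtx_sim_config`.
#' @param n_reps number of simulated replicates.
#' @param alpha experiment-wise error rate.
#' @param n_perm permutations per threshold.
#' @param seed master seed; every replicate derives its own seeds from it.
#' @param thin_step thin the scanned markers to every `thin_step`-th
#'   (causal loci always kept); `1` scans the full map. QTT predictors are
#'   independent across markers, so their map is generated thinned.
#' @param window detection window in markers (0 = exact).
#' @param pair_scope 2D scope (see [scan_2d()]).
#' @param estimate_effects also run MINQUE/AUP per replicate.
#' @param verbose print one line per replicate.
#' @return An object of class `qtx_power`: list with data frames
#'   `per_locus` (`marker`, `h2_a`, `power`, and estimate summaries when
#'   requested) and `per_pair`, plus the configuration used.
#' @export
power_experiment <- function(config, n_reps = 50L, alpha = 0.05,
                             n_perm = 200L, seed = 1L, thin_step = 5L,
                             window = 0L,
                             pair_scope = c("selected", "all"),
                             estimate_effects = FALSE, verbose = FALSE) {
  pair_scope <- match.arg(pair_scope)
  seeds <- make_seeds(seed, 3L * n_reps + 1L)
  loci <- config$qts$marker
  np <- nrow(config$pairs)
  det_l <- matrix(FALSE, n_reps, length(loci))
  det_p <- matrix(FALSE, n_reps, max(np, 1L))
  est_a <- matrix(NA_real_, n_reps, length(loci))
  est_aa <- matrix(NA_real_, n_reps, max(np, 1L))

  map <- config$map
  if (config$mode == "qtt" && thin_step > 1L) {
    # transcript predictors are independent: generate the thinned panel
    keep <- union(map$marker[seq(1L, nrow(map), by = thin_step)],
                  c(loci, config$pairs$marker1, config$pairs$marker2))
    map <- map[map$marker %in% keep, , drop = FALSE]
    config$map <- map
    thin_step <- 1L
  }

  for (rep in seq_len(n_reps)) {
    s <- seeds[3L * (rep - 1L) + 1:3]
    geno <- if (config$mode == "qts")
      simulate_ril_genotypes(config$map, config$n_genotypes,
                             config$mating, seed = s[1L])
    else simulate_expression_population(config, seed = s[1L])
    truth <- calibrate_effects(config, geno)
    pheno <- simulate_phenotypes(config, geno, truth, seed = s[2L])
    th <- if (thin_step > 1L)
      thin_markers(geno, config$map, step = thin_step,
                   keep = c(loci, config$pairs$marker1,
                            config$pairs$marker2))
    else list(geno = geno, map = config$map)

    sc1 <- scan_1d(th$geno, pheno)
    thr1 <- permutation_threshold(th$geno, pheno, "1d", alpha = alpha,
                                  n_perm = n_perm, seed = s[3L])
    sel <- find_peaks(sc1, th$map, thr1$critical_F)
    sc2 <- NULL; thr2 <- NULL
    if (np && length(sel)) {
      sc2 <- scan_2d(th$geno, pheno, selected = sel, scope = pair_scope)
      thr2 <- permutation_threshold(th$geno, pheno, "2d", alpha = alpha,
                                    n_perm = n_perm, seed = s[3L],
                                    selected = sel,
                                    pair_scope = pair_scope)
    }
    cs <- stepwise_select(th$geno, pheno, sc1, thr1, sc2, thr2, th$map)

    det_l[rep, ] <- vapply(loci, function(mk)
      any(marker_match(cs$loci$marker, mk, th$map, window)), TRUE)
    if (np) det_p[rep, ] <- vapply(seq_len(np), function(i)
      pair_detected(cs$pairs, config$pairs$marker1[i],
                    config$pairs$marker2[i], th$map, window), TRUE)

    if (estimate_effects && (nrow(cs$loci) || nrow(cs$pairs))) {
      d <- build_design(th$geno, pheno, loci = cs$loci$marker,
                        pairs = as.matrix(cs$pairs[, 1:2]))
      vc <- minque1(d)
      eff <- aup_predict(d, vc = vc)
      ai <- match(loci, eff$locus1[eff$class == "A"])
      est_a[rep, ] <- eff$estimate[eff$class == "A"][ai]
      if (np) {
        key <- paste(eff$locus1, eff$locus2)[eff$class == "AA"]
        pi <- match(paste(config$pairs$marker1, config$pairs$marker2), key)
        est_aa[rep, ] <- eff$estimate[eff$class == "AA"][pi]
      }
    }
    if (verbose)
      message(sprintf("replicate %d/%d: %d loci, %d pairs retained",
                      rep, n_reps, nrow(cs$loci), nrow(cs$pairs)))
  }

  per_locus <- data.frame(marker = loci, h2_a = config$qts$h2_a,
                          power = 100 * colMeans(det_l),
                          stringsAsFactors = FALSE)
  per_pair <- if (np)
    data.frame(marker1 = config$pairs$marker1,
               marker2 = config$pairs$marker2,
               h2_aa = config$pairs$h2_aa,
               power = 100 * colMeans(det_p),
               stringsAsFactors = FALSE)
  else data.frame()
  if (estimate_effects) {
    per_locus$mean_est <- colMeans(est_a, na.rm = TRUE)
    per_locus$se_est <- apply(est_a, 2L, stats::sd, na.rm = TRUE)
    if (np) {
      per_pair$mean_est <- colMeans(est_aa, na.rm = TRUE)
      per_pair$se_est <- apply(est_aa, 2L, stats::sd, na.rm = TRUE)
    }
  }
  structure(list(per_locus = per_locus, per_pair = per_pair,
                 n_reps = n_reps, alpha = alpha, n_perm = n_perm,
                 seed = seed, mode = config$mode),
            class = "qtx_power")
}

# is any marker in `found` within `window` markers of `target` on the map?
marker_match <- function(found, target, map, window = 0L) {
  if (length(found) == 0L) return(FALSE)
  if (window == 0L || is.null(map)) return(target %in% found)
  it <- match(target, map$marker)
  idx <- match(found, map$marker)
  ok <- !is.na(idx) & map$chrom[idx] == map$chrom[it] &
    abs(idx - it) <= window
  any(ok, na.rm = TRUE)
}

pair_detected <- function(pairs_df, m1, m2, map, window = 0L) {
  if (nrow(pairs_df) == 0L) return(FALSE)
  any(vapply(seq_len(nrow(pairs_df)), function(r) {
    a <- pairs_df$marker_i[r]; b <- pairs_df$marker_j[r]
    (marker_match(a, m1, map, window) && marker_match(b, m2, map, window)) ||
      (marker_match(a, m2, map, window) && marker_match(b, m1, map, window))
  }, TRUE))
}

#' @export
print.qtx_power <- function(x, ...) {
  cat(sprintf("qtx_power (%s): %d replicates, alpha %g, %d permutations\n",
              x$mode, x$n_reps, x$alpha, x$n_perm))
  cat("per-locus power (%):\n"); print(x$per_locus, ...)
  if (nrow(x$per_pair)) { cat("per-pair power (%):\n"); print(x$per_pair, ...) }
  invisible(x)
}
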