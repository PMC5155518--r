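# Monte Carlo simulator: RIL genotypes on a BXD-like genetic map and
# multi-environment phenotypes with additive, epistatic, GxE and
# epistasis-x-E architecture at specified heritabilities.

#' BXD-like default genetic map
#'
#' 20 chromosomes of 101.88 cM each carrying 116 equally spaced markers:
#' 2,320 markers covering 2,037.6 cM in total, emulating the density of the
#' BXD mouse marker panel.
#'
#' @param n_chr,markers_per_chr,chr_len_cM map geometry.
#' @return a `qtx_map`.
#' @export
default_map <- function(n_chr = 20L, markers_per_chr = 116L,
                        chr_len_cM = 101.88) {
  marker <- character(0); chrom <- character(0); cM <- numeric(0)
  for (c in seq_len(n_chr)) {
    marker <- c(marker, sprintf("c%02dm%03d", c, seq_len(markers_per_chr)))
    chrom <- c(chrom, rep(sprintf("chr%02d", c), markers_per_chr))
    cM <- c(cM, seq(0, chr_len_cM, length.out = markers_per_chr))
  }
  genetic_map(marker, chrom, cM)
}

#' Haldane recombination fraction
#'
#' `r = (1 - exp(-2d/100))/2` for a map distance `d` in centimorgans.
#' @param d map distance in cM.
#' @export
haldane_r <- function(d) (1 - exp(-2 * d / 100)) / 2

#' RIL-expanded recombination fraction
#'
#' Repeated inbreeding expands the observed recombination between fixed
#' lines: `R = 4r/(1 + 6r)` for sib-mated RILs (the BXD panel) and
#' `R = 2r/(1 + 2r)` for selfed RILs.
#'
#' @param r meiotic recombination fraction.
#' @param mating `"sib_mating"` or `"selfing"`.
#' @export
ril_expansion <- function(r, mating = c("sib_mating", "selfing")) {
  mating <- match.arg(mating)
  if (mating == "sib_mating") 4 * r / (1 + 6 * r) else 2 * r / (1 + 2 * r)
}

#' Simulate RIL genotypes along a genetic map
#'
#' Each chromosome is an independent two-state Markov chain over the coded
#' homozygotes \{+1, -1\}: the first marker is +/-1 with probability 1/2
#' and adjacent markers recombine with the RIL-expanded fraction of their
#' Haldane distance. Bit-reproducible given `seed`.
#'
#' @param map a `qtx_map`.
#' @param n number of genotypes (lines).
#' @param mating RIL mating system (see [ril_expansion()]).
#' @param seed integer seed.
#' @return a `qtx_geno` in categorical mode.
#' @export
simulate_ril_genotypes <- function(map, n = 200L,
                                   mating = c("sib_mating", "selfing"),
                                   seed = NULL) {
  mating <- match.arg(mating)
  m <- nrow(map)
  X <- matrix(0, n, m, dimnames = list(sprintf("RIL%03d", seq_len(n)),
                                       map$marker))
  with_seed(seed, {
    for (ch in unique(map$chrom)) {
      cols <- which(map$chrom == ch)
      R <- ril_expansion(haldane_r(diff(map$cM[cols])), mating)
      X[, cols[1L]] <- sample(c(1, -1), n, replace = TRUE)
      for (k in seq_along(R)) {
        flip <- stats::runif(n) < R[k]
        X[, cols[k + 1L]] <- X[, cols[k]] * ifelse(flip, -1, 1)
      }
    }
  })
  genotype_matrix(X, mode = "categorical_homozygote")
}

#' Simulation configuration
#'
#' Bundles the genetic architecture of a simulated mapping experiment: the
#' map, population and environment sizes, and the heritability assigned to
#' every genetic term. Heritabilities are fractions of the phenotypic
#' variance; their sum must equal `total_h2`.
#'
#' @param map a `qtx_map`.
#' @param qts data frame with columns `marker`, `h2_a` (additive
#'   heritability) and `h2_ae` (total locus-by-environment heritability).
#' @param pairs data frame with columns `marker1`, `marker2`, `h2_aa`,
#'   `h2_aae`.
#' @param n_genotypes number of lines.
#' @param environments number of environments `H`.
#' @param reps_per_env replicate observations per genotype in each
#'   environment.
#' @param mating RIL mating system.
#' @param total_h2 total genetic heritability (default 0.20).
#' @param phenotypic_variance total phenotypic variance (default 100).
#' @param mu population mean.
#' @param env_effects fixed environment effects (length `H`; default
#'   centered, equally spaced with a spread of one phenotypic SD).
#' @param mode `"qts"` (coded RIL SNPs) or `"qtt"` (continuous
#'   transcript-like predictors).
#' @param seed seed for the architecture draws (effect signs, GxE
#'   patterns), fixed across replicate datasets.
#' @return list of class `qtx_sim_config`.
#' @export
sim_config <- function(map, qts, pairs = NULL, n_genotypes = 200L,
                       environments = 3L, reps_per_env = 5L,
                       mating = "sib_mating", total_h2 = 0.20,
                       phenotypic_variance = 100, mu = 10,
                       env_effects = NULL, mode = c("qts", "qtt"),
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "qtx_map"))
  if (is.null(pairs))
    pairs <- data.frame(marker1 = character(0), marker2 = character(0),
                        h2_aa = numeric(0), h2_aae = numeric(0))
  tot <- sum(qts$h2_a) + sum(qts$h2_ae) + sum(pairs$h2_aa) + sum(pairs$h2_aae)
  if (abs(tot - total_h2) > 1e-8)
    stop(sprintf("genetic heritabilities sum to %.4f, not total_h2 = %.4f",
                 tot, total_h2))
  if (total_h2 > 1) stop("total_h2 must be <= 1")
  named <- c(qts$marker, pairs$marker1, pairs$marker2)
  if (!all(named %in% map$marker))
    stop("simulated locus not on map: ", setdiff(named, map$marker)[1L])
  H <- as.integer(environments)
  if (is.null(env_effects))
    env_effects <- if (H > 1L)
      (seq_len(H) - (H + 1) / 2) / (H - 1) * 2 * sqrt(phenotypic_variance) / 2
  else 0
  stopifnot(length(env_effects) == H)
  structure(list(map = map, qts = qts, pairs = pairs,
                 n_genotypes = as.integer(n_genotypes),
                 environments = H, reps_per_env = as.integer(reps_per_env),
                 mating = mating, total_h2 = total_h2,
                 phenotypic_variance = phenotypic_variance, mu = mu,
                 env_effects = env_effects, mode = mode,
                 seed = as.integer(seed)),
            class = "qtx_sim_config")
}

#' Default QTS simulation design
#'
#' The package's reference Monte Carlo design: 200 RIL genotypes on the
#' BXD-like map, three environments with five replicate observations per
#' genotype and environment, five additive QTSs placed mid-chromosome on
#' chromosomes 1-5, and three epistatic pairs Q1xQ3, Q1xQ4, Q3xQ4, with
#' total heritability 20% of a phenotypic variance of 100. Additive
#' heritabilities are 2.33, 1.77, 2.00, 3.63 and 1.31%; each locus carries
#' 0.20% locus-by-environment heritability, each pair 2.40% epistatic and
#' about 0.25% epistasis-by-environment heritability. See the methods
#' vignette for how this allocation was fixed.
#'
#' @param map a `qtx_map` (default [default_map()]).
#' @param seed architecture seed.
#' @param ... overrides passed on to [sim_config()].
#' @export
qts_sim_config <- function(map = default_map(), seed = 1L, ...) {
  loci <- sprintf("c%02dm058", 1:5)
  qts <- data.frame(marker = loci,
                    h2_a = c(2.33, 1.77, 2.00, 3.63, 1.31) / 100,
                    h2_ae = rep(0.20, 5) / 100,
                    stringsAsFactors = FALSE)
  pairs <- data.frame(marker1 = loci[c(1, 1, 3)],
                      marker2 = loci[c(3, 4, 4)],
                      h2_aa = rep(2.40, 3) / 100,
                      h2_aae = rep(0.76 / 3, 3) / 100,
                      stringsAsFactors = FALSE)
  sim_config(map, qts, pairs, mode = "qts", seed = seed, ...)
}

#' Default QTT simulation design
#'
#' Continuous-predictor variant: 200 genotypes each carrying 2,320
#' transcript-like standard-normal predictors on the same map, four causal
#' transcripts plus three causal pairs, total heritability 20%.
#'
#' @inheritParams qts_sim_config
#' @export
qtt_sim_config <- function(map = default_map(), seed = 1L, ...) {
  loci <- sprintf("c%02dm058", 1:4)
  qts <- data.frame(marker = loci,
                    h2_a = c(2.5, 2.0, 3.0, 1.5) / 100,
                    h2_ae = rep(0.25, 4) / 100,
                    stringsAsFactors = FALSE)
  pairs <- data.frame(marker1 = loci[c(1, 1, 3)],
                      marker2 = loci[c(3, 4, 4)],
                      h2_aa = rep(3.0, 3) / 100,
                      h2_aae = rep(1 / 3, 3) / 100,
                      stringsAsFactors = FALSE)
  sim_config(map, qts, pairs, mode = "qtt", seed = seed, ...)
}

#' Simulate a continuous "transcript" predictor population
#'
#' Each column is an independent standard-normal transcript abundance
#' (standardized to zero mean and unit variance), indexed by the same
#' marker ids as the map.
#'
#' @param config a `qtx_sim_config` with `mode = "qtt"`.
#' @param seed integer seed.
#' @return a `qtx_geno` in continuous mode.
#' @export
simulate_expression_population <- function(config, seed = NULL) {
  m <- nrow(config$map)
  n <- config$n_genotypes
  vals <- with_seed(seed, matrix(stats::rnorm(n * m), n, m))
  dimnames(vals) <- list(sprintf("G%03d", seq_len(n)), config$map$marker)
  genotype_matrix(vals, mode = "continuous", standardize = TRUE)
}

#' Calibrate genetic effect sizes from target heritabilities
#'
#' Converts the configured heritabilities into effect sizes on the trait
#' scale: additive `a_i = s_i sqrt(h2_i Vp)` (coded predictors have unit
#' variance by construction), epistatic
#' `aa_ij = s_ij sqrt(h2_ij Vp / Var(x_i x_j))` with the empirical product
#' variance, and environment-interaction effects drawn once per
#' configuration (fixed across replicate datasets) to sum to zero across
#' environments with mean square `h2_ae Vp` (likewise for `aae`). Signs
#' `s` alternate across loci and are recorded. The residual variance is
#' `Vp (1 - total_h2)`.
#'
#' @param config a `qtx_sim_config`.
#' @param geno the genotype matrix the effects will act on.
#' @return list of class `qtx_truth` with elements `a`, `aa`, `ae`
#'   (loci x environments), `aae` (pairs x environments), `sigma2_res`.
#' @export
calibrate_effects <- function(config, geno) {
  vp <- config$phenotypic_variance
  H <- config$environments
  nl <- nrow(config$qts)
  np <- nrow(config$pairs)
  X <- geno$values
  signs_a <- rep_len(c(1, -1), nl)
  signs_aa <- rep_len(c(1, -1), np)
  a <- signs_a * sqrt(config$qts$h2_a * vp)
  aa <- numeric(np)
  if (np) {
    pv <- vapply(seq_len(np), function(i)
      stats::var(X[, config$pairs$marker1[i]] * X[, config$pairs$marker2[i]]),
      0)
    aa <- signs_aa * sqrt(config$pairs$h2_aa * vp / pv)
  }
  draw_gxe <- function(h2s) {
    E <- matrix(0, length(h2s), H)
    if (H > 1L) for (i in seq_along(h2s)) {
      g <- stats::rnorm(H)
      g <- g - mean(g)
      ms <- mean(g^2)
      E[i, ] <- if (ms > 0) g / sqrt(ms) * sqrt(h2s[i] * vp) else 0
    }
    E
  }
  out <- with_seed(config$seed, {
    ae <- draw_gxe(config$qts$h2_ae)
    aae <- draw_gxe(config$pairs$h2_aae)
    list(ae = ae, aae = aae)
  })
  structure(list(a = stats::setNames(a, config$qts$marker),
                 aa = aa, ae = out$ae, aae = out$aae,
                 loci = config$qts$marker,
                 pair1 = config$pairs$marker1, pair2 = config$pairs$marker2,
                 sigma2_res = vp * (1 - config$total_h2)),
            class = "qtx_truth")
}

#' Simulate multi-environment phenotypes from calibrated effects
#'
#' Generates the observation-level phenotype
#' \deqn{y_{hk} = \mu + e_h + \sum_i a_i x_{ik} + \sum_{i<j} aa_{ij} x_{ik}
#'   x_{jk} + \sum_i ae_{hi} x_{ik} + \sum_{i<j} aae_{hij} x_{ik} x_{jk} +
#'   \epsilon_{hk}}
#' with every genotype observed in every environment (`reps_per_env`
#' replicate observations per cell) and Gaussian residuals. The total
#' genetic value of each record is attached as the `"genetic"` attribute,
#' so the realized heritability is available via [realized_h2()].
#'
#' @param config a `qtx_sim_config`.
#' @param geno genotypes the phenotypes are generated from.
#' @param truth effect sizes from [calibrate_effects()].
#' @param seed integer seed (residual and nothing else).
#' @return a `qtx_pheno`.
#' @export
simulate_phenotypes <- function(config, geno, truth, seed = NULL) {
  X <- geno$values
  n <- nrow(X)
  H <- config$environments
  r <- config$reps_per_env
  g_main <- if (length(truth$a))
    as.vector(X[, truth$loci, drop = FALSE] %*% truth$a) else numeric(n)
  P <- if (length(truth$aa))
    X[, truth$pair1, drop = FALSE] * X[, truth$pair2, drop = FALSE] else NULL
  if (!is.null(P)) g_main <- g_main + as.vector(P %*% truth$aa)
  g_env <- matrix(g_main, n, H)
  if (H > 1L) {
    if (length(truth$a))
      g_env <- g_env + X[, truth$loci, drop = FALSE] %*% truth$ae
    if (!is.null(P)) g_env <- g_env + P %*% truth$aae
  }
  idx_g <- rep(rep(seq_len(n), each = r), H)
  idx_h <- rep(seq_len(H), each = n * r)
  gval <- g_env[cbind(idx_g, idx_h)]
  eps <- with_seed(seed,
                   stats::rnorm(length(gval), 0, sqrt(truth$sigma2_res)))
  y <- config$mu + config$env_effects[idx_h] + gval + eps
  ph <- phenotype_table(rownames(X)[idx_g], sprintf("E%d", idx_h), y)
  attr(ph, "genetic") <- gval
  ph
}

#' Realized genetic fraction of the phenotypic variance
#'
#' Variance of the genetic values across records divided by the variance of
#' the phenotype after removing environment means (fixed environment
#' effects are not part of the phenotypic variance that heritability
#' refers to).
#'
#' @param pheno a `qtx_pheno` produced by [simulate_phenotypes()].
#' @export
realized_h2 <- function(pheno) {
  g <- attr(pheno, "genetic")
  if (is.null(g)) stop("phenotype table carries no genetic values")
  yc <- pheno$value - stats::ave(pheno$value, pheno$environment)
  stats::var(g) / stats::var(yc)
}
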