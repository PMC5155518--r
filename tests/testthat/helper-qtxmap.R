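# shared fixture builders (everything generated in code)

# small genetic map: `chr` chromosomes with `m` markers each, 10 cM apart
h_map <- function(chr = 2L, m = 4L, spacing = 10) {
  genetic_map(marker = paste0("m", seq_len(chr * m)),
              chrom = rep(as.character(seq_len(chr)), each = m),
              cM = rep(seq(0, by = spacing, length.out = m), chr))
}

# random RIL genotypes + pure-noise multi-environment phenotypes
h_rand_data <- function(n_ind = 12L, chr = 2L, m = 4L, H = 3L, reps = 2L,
                        seed = 1L, sd = 3) {
  map <- h_map(chr, m)
  geno <- simulate_ril_genotypes(map, n = n_ind, seed = seed)
  ids <- rownames(geno$values)
  pheno <- with_test_seed(seed + 1L, phenotype_table(
    rep(rep(ids, each = reps), H),
    rep(sprintf("E%d", seq_len(H)), each = n_ind * reps),
    rnorm(n_ind * reps * H, 10, sd)))
  list(geno = geno, pheno = pheno, map = map)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# independent nested-model F oracle via two least-squares fits
h_ls_f <- function(y, full, reduced) {
  qf <- qr(as.matrix(full)); qr_ <- qr(as.matrix(reduced))
  rss_f <- sum(qr.resid(qf, y)^2)
  rss_r <- sum(qr.resid(qr_, y)^2)
  df1 <- qf$rank - qr_$rank
  df2 <- length(y) - qf$rank
  list(F = ((rss_r - rss_f) / df1) / (rss_f / df2), df1 = df1, df2 = df2)
}

# design columns of one locus (main + per-environment interaction)
h_locus_cols <- function(geno, pheno, locus) {
  d <- build_design(geno, pheno, loci = locus)
  cbind(d$blocks$A, d$blocks$AE)
}
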