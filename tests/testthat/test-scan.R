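test_that("the 1D scan reproduces the projector-based F at every locus", {
  for (H in c(1L, 3L)) {
    dat <- h_rand_data(n_ind = 10L, chr = 2L, m = 4L, H = H, reps = 2L,
                       seed = 30L + H)
    d0 <- build_design(dat$geno, dat$pheno)
    for (joint in c(TRUE, FALSE)) {
      sc <- scan_1d(dat$geno, dat$pheno, joint = joint)
      for (mk in sc$marker) {
        cols <- if (joint) h_locus_cols(dat$geno, dat$pheno, mk) else
          build_design(dat$geno, dat$pheno, loci = mk)$blocks$A
        f <- henderson_f(dat$pheno$value, cbind(d0$X, cols), d0$X)
        i <- match(mk, sc$marker)
        expect_equal(sc$untestable[i], f$untestable)
        if (!f$untestable) {
          expect_equal(sc$F[i], f$F, tolerance = 1e-8)
          expect_equal(sc$df_num[i], f$df_num)
          expect_equal(sc$df_den[i], f$df_den)
        }
      }
    }
  }
})

test_that("the 1D scan handles continuous predictors identically", {
  with_test_seed(41, {
    vals <- matrix(rnorm(20 * 6), 20, 6,
                   dimnames = list(paste0("i", 1:20), paste0("t", 1:6)))
    g <- genotype_matrix(vals, mode = "continuous")
    ph <- phenotype_table(rep(rownames(vals), 2),
                          rep(c("E1", "E2"), each = 20), rnorm(40))
  })
  sc <- scan_1d(g, ph)
  d0 <- build_design(g, ph)
  f <- henderson_f(ph$value, cbind(d0$X, h_locus_cols(g, ph, "t3")), d0$X)
  expect_equal(sc$F[3], f$F, tolerance = 1e-8)
})

test_that("monomorphic markers are untestable and the scan continues", {
  dat <- h_rand_data(seed = 8L)
  dat$geno$values[, "m2"] <- 1
  sc <- scan_1d(dat$geno, dat$pheno)
  expect_true(sc$untestable[sc$marker == "m2"])
  expect_false(any(sc$untestable[sc$marker != "m2"]))
})

test_that("the exhaustive 2D scan matches the nested least-squares oracle", {
  # 20 markers x 60 observations, every pair checked against two lm fits
  dat <- h_rand_data(n_ind = 20L, chr = 4L, m = 5L, H = 3L, reps = 1L,
                     seed = 55L)
  sc2 <- scan_2d(dat$geno, dat$pheno, scope = "all")
  expect_equal(nrow(sc2), 20 * 19 / 2)
  d0 <- build_design(dat$geno, dat$pheno)
  y <- dat$pheno$value
  for (r in seq_len(nrow(sc2))) {
    mi <- sc2$marker_i[r]; mj <- sc2$marker_j[r]
    d <- build_design(dat$geno, dat$pheno, loci = c(mi, mj),
                      pairs = matrix(c(mi, mj), 1))
    red <- cbind(d$X, d$blocks$A, d$blocks$AE)
    full <- cbind(red, d$blocks$AA, d$blocks$AAE)
    f <- henderson_f(y, full, red)
    expect_equal(sc2$untestable[r], f$untestable,
                 label = paste(mi, mj, "testability"))
    if (!f$untestable)
      expect_equal(sc2$F[r], f$F, tolerance = 1e-7,
                   label = paste(mi, mj, "F"))
  }
})

test_that("perfectly correlated loci give an untestable pair", {
  dat <- h_rand_data(n_ind = 12L, seed = 3L)
  dat$geno$values[, "m5"] <- dat$geno$values[, "m1"]
  sc2 <- scan_2d(dat$geno, dat$pheno, scope = "all")
  r <- which(sc2$marker_i == "m1" & sc2$marker_j == "m5")
  expect_true(sc2$untestable[r])
})

test_that("scan results do not depend on marker order", {
  dat <- h_rand_data(n_ind = 14L, seed = 12L)
  sc <- scan_1d(dat$geno, dat$pheno)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  g2 <- dat$geno
  g2$values <- g2$values[, perm]
  g2$monomorphic <- g2$monomorphic[perm]
  sc2 <- scan_1d(g2, dat$pheno)
  expect_equal(sc2$F[match(sc$marker, sc2$marker)], sc$F)
})

test_that("the selected-scope 2D scan covers each canonical pair once", {
  dat <- h_rand_data(n_ind = 12L, seed = 19L)
  sc2 <- scan_2d(dat$geno, dat$pheno, selected = c("m2", "m6"),
                 scope = "selected")
  keys <- paste(sc2$marker_i, sc2$marker_j)
  expect_false(any(duplicated(keys)))
  expect_equal(nrow(sc2), 7 + 6)  # m2 x 7 others + m6 x remaining 6
  all2 <- scan_2d(dat$geno, dat$pheno, scope = "all")
  shared <- match(keys, paste(all2$marker_i, all2$marker_j))
  expect_equal(sc2$F, all2$F[shared])
})

test_that("permutation thresholds are reproducible and follow the quantile rule", {
  dat <- h_rand_data(n_ind = 16L, seed = 61L)
  t1 <- permutation_threshold(dat$geno, dat$pheno, "1d", n_perm = 40,
                              seed = 7)
  t2 <- permutation_threshold(dat$geno, dat$pheno, "1d", n_perm = 40,
                              seed = 7)
  expect_identical(t1$max_F_null, t2$max_F_null)
  expect_identical(t1$critical_F, t2$critical_F)
  # conservative higher-quantile convention
  expect_equal(t1$critical_F,
               sort(t1$max_F_null, decreasing = TRUE)[max(1, floor(0.05 * 40))])
  t3 <- suppressWarnings(permutation_threshold(dat$geno, dat$pheno, "1d",
                                               n_perm = 1, seed = 9))
  expect_equal(t3$critical_F, t3$max_F_null)
  expect_warning(permutation_threshold(dat$geno, dat$pheno, "1d",
                                       n_perm = 10, seed = 1), "coarse")
})

test_that("2D permutation thresholds are reproducible", {
  dat <- h_rand_data(n_ind = 12L, seed = 62L)
  t1 <- permutation_threshold(dat$geno, dat$pheno, "2d", n_perm = 25,
                              seed = 3, selected = "m1",
                              pair_scope = "selected")
  t2 <- permutation_threshold(dat$geno, dat$pheno, "2d", n_perm = 25,
                              seed = 3, selected = "m1",
                              pair_scope = "selected")
  expect_identical(t1$max_F_null, t2$max_F_null)
  expect_true(all(t1$max_F_null >= 0))
})

test_that("peak finding respects chromosomes, ends, ties and thresholds", {
  map <- h_map(chr = 2L, m = 4L)
  sc <- data.frame(marker = map$marker,
                   F = c(1, 5, 2, 1,  4, 4, 1, 9),
                   untestable = FALSE)
  pk <- find_peaks(sc, map)
  # chr1: m2; chr2: plateau 4,4 -> lower position m5; end peak m8
  expect_setequal(pk, c("m2", "m5", "m8"))
  expect_equal(find_peaks(sc, map, critical_F = 4.5), c("m8", "m2"))
  sc$F[2] <- NA; sc$untestable[2] <- TRUE
  expect_false("m2" %in% find_peaks(sc, map))
})
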