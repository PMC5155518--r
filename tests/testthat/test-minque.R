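# a one-way random-effects design wrapped as a qtx_design
h_oneway_design <- function(g, r, seed = 1) {
  n <- g * r
  grp <- factor(rep(seq_len(g), each = r))
  U <- stats::model.matrix(~ grp - 1)
  colnames(U) <- paste0("g", seq_len(g))
  with_test_seed(seed, {
    u <- rnorm(g, 0, 2)
    y <- 5 + u[grp] + rnorm(n, 0, 1.5)
  })
  d <- structure(list(
    X = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
    blocks = list(A = U),
    terms = list(A = data.frame(class = "A", locus1 = colnames(U),
                                locus2 = NA_character_,
                                environment = NA_character_)),
    y = y, env = factor(rep("E1", n)), env_levels = "E1",
    individuals = as.character(seq_len(n)), kinship = NULL,
    mode = "categorical_homozygote"), class = "qtx_design")
  list(design = d, y = y, grp = grp)
}

test_that("MINQUE(1) equals the ANOVA estimators on balanced one-way layouts", {
  for (case in list(c(g = 6, r = 4), c(g = 10, r = 3), c(g = 4, r = 12))) {
    ow <- h_oneway_design(case["g"], case["r"], seed = sum(case))
    vc <- minque1(ow$design)
    ms <- anova(lm(ow$y ~ ow$grp))$`Mean Sq`
    expect_equal(vc$sigma2_raw[["A"]], (ms[1] - ms[2]) / case[["r"]],
                 tolerance = 1e-8)
    expect_equal(vc$sigma2_raw[["residual"]], ms[2], tolerance = 1e-8)
  }
})

test_that("a response inside the fixed space yields all-zero components", {
  dat <- h_rand_data(n_ind = 10L, H = 3L, reps = 2L, seed = 14L)
  d <- build_design(dat$geno, dat$pheno, loci = c("m1", "m4"))
  y <- as.vector(d$X %*% c(3, 1, -1))
  vc <- minque1(d, y)
  expect_equal(unname(vc$sigma2), rep(0, length(vc$sigma2)), tolerance = 1e-10)
  eff <- aup_predict(d, y, vc)
  expect_equal(eff$estimate, rep(0, nrow(eff)), tolerance = 1e-8)
})

test_that("Q annihilates the fixed design", {
  dat <- h_rand_data(n_ind = 12L, seed = 15L)
  d <- build_design(dat$geno, dat$pheno, loci = c("m2", "m7"),
                    pairs = matrix(c("m2", "m7"), 1))
  vc <- minque1(d)
  expect_lt(max(abs(vc$Q %*% d$X)), 1e-10)
})

test_that("scaling the response scales every component quadratically", {
  dat <- h_rand_data(n_ind = 15L, seed = 16L)
  d <- build_design(dat$geno, dat$pheno, loci = c("m1", "m5"))
  vc1 <- minque1(d)
  vc2 <- minque1(d, 2.5 * d$y)
  expect_equal(vc2$sigma2_raw, 2.5^2 * vc1$sigma2_raw, tolerance = 1e-8)
})

test_that("negative solutions are truncated but kept in sigma2_raw", {
  # tiny between-group variance drives the raw estimate negative sometimes
  found <- FALSE
  for (s in 1:20) {
    ow <- h_oneway_design(5, 3, seed = 200 + s)
    y0 <- with_test_seed(300 + s, rnorm(15))
    vc <- minque1(ow$design, y0)
    if (any(vc$sigma2_raw < 0)) {
      found <- TRUE
      expect_true(all(vc$sigma2 >= 0))
      expect_true(any(vc$truncated))
      break
    }
  }
  expect_true(found)
})

test_that("collinear random blocks are reported as singular", {
  ow <- h_oneway_design(6, 4)
  d <- ow$design
  d$blocks$AA <- d$blocks$A
  tAA <- d$terms$A
  tAA$class <- "AA"
  d$terms$AA <- tAA
  expect_error(minque1(d), "singular|collinear")
})

test_that("the AUP class-variance identity holds exactly", {
  dat <- h_rand_data(n_ind = 25L, H = 3L, reps = 2L, seed = 17L)
  d <- build_design(dat$geno, dat$pheno, loci = c("m1", "m3", "m6"),
                    pairs = matrix(c("m1", "m6"), 1))
  ridx <- match(dat$pheno$individual, rownames(dat$geno$values))
  y <- dat$pheno$value + 2 * dat$geno$values[ridx, "m1"]
  vc <- minque1(d, y)
  eff <- aup_predict(d, y, vc)
  for (cl in setdiff(names(vc$sigma2), "residual")) {
    if (vc$sigma2[[cl]] > 0) {
      e <- eff$estimate[eff$class == cl]
      expect_equal(mean(e^2), vc$sigma2[[cl]], tolerance = 1e-8)
    }
  }
})

test_that("jackknife standard errors are finite and positive for real signal", {
  dat <- h_rand_data(n_ind = 20L, H = 2L, reps = 2L, seed = 18L)
  d <- build_design(dat$geno, dat$pheno, loci = c("m2", "m5"))
  ridx <- match(dat$pheno$individual, rownames(dat$geno$values))
  y <- dat$pheno$value + 3 * dat$geno$values[ridx, "m2"]
  vc <- minque1(d, y)
  eff <- aup_predict(d, y, vc, se = "jackknife", jackknife_groups = 10)
  a <- eff[eff$class == "A", ]
  expect_true(all(is.finite(a$se) & a$se > 0))
  expect_true(all(a$p >= 0 & a$p <= 1))
  expect_lt(a$p[a$locus1 == "m2"], 0.05)
})

test_that("the heritability report decomposes to one", {
  dat <- h_rand_data(n_ind = 18L, seed = 19L)
  d <- build_design(dat$geno, dat$pheno, loci = c("m1", "m8"))
  vc <- minque1(d)
  eff <- aup_predict(d, vc = vc)
  rep_ <- heritability_report(vc, eff, d)
  cls <- rep_[rep_$class %in% c("A", "AE", "residual"), ]
  expect_equal(sum(cls$h2), 1, tolerance = 1e-10)
  expect_true(all(rep_$h2 >= 0))
})
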