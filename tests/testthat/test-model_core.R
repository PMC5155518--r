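test_that("genotype coding maps homozygote symbols to +1/-1/0", {
  raw <- matrix(c("QQ", "Qq", "qq", "QQ"), 2, 2,
                dimnames = list(c("i1", "i2"), c("m1", "m2")))
  g <- code_genotypes(raw)
  expect_identical(g$values, matrix(c(1, 0, -1, 1), 2, 2,
                                    dimnames = dimnames(raw)))
  expect_equal(g$mode, "categorical_homozygote")

  panel <- matrix(c("QQ", "qq", "Qq", "QQ"), 2, 2, byrow = TRUE)
  expect_equal(unname(code_genotypes(panel)$values),
               matrix(c(1, -1, 0, 1), 2, 2, byrow = TRUE))
})

test_that("monomorphic columns are allowed but flagged", {
  raw <- matrix(c("QQ", "QQ", "QQ", "qq"), 2, 2,
                dimnames = list(NULL, c("mono", "poly")))
  g <- code_genotypes(raw)
  expect_true(all(g$values[, "mono"] == 1))
  expect_identical(unname(g$monomorphic), c(TRUE, FALSE))
})

test_that("unknown symbols raise an error naming the cell", {
  raw <- matrix(c("QQ", "XX"), 1, 2,
                dimnames = list("indA", c("m1", "m2")))
  expect_error(code_genotypes(raw), "XX.*indA.*m2")
})

test_that("missing calls are mean-imputed by default, kept as NA on request", {
  raw <- matrix(c("QQ", "--", "qq", "QQ", "qq", "qq"), 3, 2,
                dimnames = list(NULL, c("m1", "m2")))
  g <- code_genotypes(raw)
  expect_equal(unname(g$values[2, 1]), 0)  # mean of (+1, -1)
  g2 <- code_genotypes(raw, missing = "keep")
  expect_true(is.na(g2$values[2, 1]))
})

test_that("epistasis coefficient is the product coding", {
  expect_equal(epistasis_coefficient(1, 1), 1)
  expect_equal(epistasis_coefficient(-1, -1), 1)
  expect_equal(epistasis_coefficient(1, -1), -1)
  expect_equal(epistasis_coefficient(0, c(1, -1, 0.7)), c(0, 0, 0))
})

test_that("design blocks have the documented shapes and entries", {
  dat <- h_rand_data(n_ind = 6L, chr = 1L, m = 4L, H = 3L, reps = 1L)
  # one locus, H = 3, n = 18 records: A 18x1, AE 18x3 with env-masked x
  d <- build_design(dat$geno, dat$pheno, loci = "m1")
  expect_equal(dim(d$blocks$A), c(18L, 1L))
  expect_equal(dim(d$blocks$AE), c(18L, 3L))
  in_e2 <- d$env == levels(d$env)[2]
  expect_equal(d$blocks$AE[in_e2, 2], d$blocks$A[in_e2, 1])
  expect_true(all(d$blocks$AE[in_e2, c(1, 3)] == 0))

  # two loci + their pair, H = 2: widths (A, AA, AE, AAE) = (2, 1, 4, 2)
  ph2 <- dat$pheno[dat$pheno$environment %in% c("E1", "E2"), ]
  class(ph2) <- class(dat$pheno)
  d2 <- build_design(dat$geno, ph2, loci = c("m1", "m3"),
                     pairs = matrix(c("m1", "m3"), 1))
  expect_equal(unname(vapply(d2$blocks, ncol, 0L)), c(2L, 1L, 4L, 2L))
  expect_equal(unname(d2$blocks$AA[, 1]),
               unname(d2$blocks$A[, 1] * d2$blocks$A[, 2]))

  # single environment: no AE/AAE blocks
  ph1 <- dat$pheno[dat$pheno$environment == "E1", ]
  class(ph1) <- class(dat$pheno)
  d1 <- build_design(dat$geno, ph1, loci = c("m1", "m3"),
                     pairs = matrix(c("m1", "m3"), 1))
  expect_named(d1$blocks, c("A", "AA"))
})

test_that("AE columns sum over environments to the A column", {
  dat <- h_rand_data(n_ind = 8L, H = 3L, reps = 2L, seed = 4L)
  d <- build_design(dat$geno, dat$pheno, loci = c("m2", "m5"),
                    pairs = matrix(c("m2", "m5"), 1))
  for (i in 1:2) {
    cols <- which(d$terms$AE$locus1 == c("m2", "m5")[i])
    expect_equal(rowSums(d$blocks$AE[, cols]), unname(d$blocks$A[, i]))
  }
  expect_equal(rowSums(d$blocks$AAE), unname(d$blocks$AA[, 1]))
  expect_true(all(d$blocks$A %in% c(-1, 0, 1)))
})

test_that("design construction is deterministic and canonicalizes pairs", {
  dat <- h_rand_data(seed = 9L)
  d1 <- build_design(dat$geno, dat$pheno, loci = c("m1", "m4"),
                     pairs = matrix(c("m4", "m1"), 1))
  d2 <- build_design(dat$geno, dat$pheno, loci = c("m1", "m4"),
                     pairs = matrix(c("m1", "m4"), 1))
  expect_identical(d1$blocks, d2$blocks)
  expect_equal(d1$terms$AA$locus1, "m1")
})

test_that("design validation rejects bad input", {
  dat <- h_rand_data()
  expect_error(build_design(dat$geno, dat$pheno, loci = c("m1", "m1")),
               "twice")
  expect_error(build_design(dat$geno, dat$pheno, loci = "nope"), "unknown")
  expect_error(build_design(dat$geno, dat$pheno,
                            pairs = matrix(c("m1", "m1"), 1)), "distinct")
  bad <- phenotype_table("ghost", "E1", 1)
  expect_error(build_design(dat$geno, bad), "ghost")
  expect_error(phenotype_table(character(0), character(0), numeric(0)),
               "empty")
})

test_that("map validation enforces ordering and uniqueness", {
  expect_error(genetic_map(c("a", "a"), c("1", "1"), c(0, 1)), "duplicated")
  expect_error(genetic_map(c("a", "b"), c("1", "1"), c(5, 1)), "b")
  m <- genetic_map(c("a", "b"), c("1", "2"), c(5, 1))
  expect_s3_class(m, "qtx_map")
})
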