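test_that("map functions follow Haldane and RIL expansion formulas", {
  expect_equal(haldane_r(0), 0)
  expect_equal(ril_expansion(haldane_r(0)), 0)
  expect_equal(haldane_r(1e6), 0.5)
  expect_equal(ril_expansion(0.5, "sib_mating"), 0.5)
  expect_equal(ril_expansion(0.5, "selfing"), 0.5)
  expect_equal(haldane_r(10), 0.0906346, tolerance = 1e-6)
  expect_equal(ril_expansion(haldane_r(10), "sib_mating"), 0.234834,
               tolerance = 1e-6)
  expect_equal(ril_expansion(haldane_r(10), "selfing"),
               2 * 0.0906346 / (1 + 2 * 0.0906346), tolerance = 1e-6)
})

test_that("adjacent-marker switching matches the expanded fraction", {
  map <- genetic_map(c("a", "b"), c("1", "1"), c(0, 10))
  g <- simulate_ril_genotypes(map, n = 10000, seed = 42)
  R <- ril_expansion(haldane_r(10), "sib_mating")
  sw <- mean(g$values[, 1] != g$values[, 2])
  expect_lt(abs(sw - R), 3 * sqrt(R * (1 - R) / 10000))
  expect_lt(abs(cor(g$values[, 1], g$values[, 2]) - (1 - 2 * R)), 0.03)
  # zero distance: identical columns
  map0 <- genetic_map(c("a", "b"), c("1", "1"), c(5, 5))
  g0 <- simulate_ril_genotypes(map0, n = 200, seed = 1)
  expect_identical(g0$values[, 1], g0$values[, 2])
})

test_that("genotype simulation is balanced and reproducible", {
  map <- h_map(chr = 3L, m = 10L)
  g1 <- simulate_ril_genotypes(map, n = 400, seed = 7)
  g2 <- simulate_ril_genotypes(map, n = 400, seed = 7)
  expect_identical(g1$values, g2$values)
  freq <- colMeans(g1$values == 1)
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / 400) + 0.02))
  expect_true(all(g1$values %in% c(-1, 1)))
})

test_that("the default map has the documented geometry", {
  map <- default_map()
  expect_equal(nrow(map), 2320L)
  expect_equal(length(unique(map$chrom)), 20L)
  bych <- tapply(map$cM, map$chrom, max)
  expect_true(all(abs(bych - 101.88) < 1e-9))
  expect_equal(sum(bych), 2037.6)
})

test_that("effect calibration follows the stated conventions", {
  map <- h_map(chr = 5L, m = 3L, spacing = 40)
  qts <- data.frame(marker = c("m2", "m5", "m8"),
                    h2_a = c(0.0233, 0.05, 0),
                    h2_ae = c(0, 0, 0))
  pairs <- data.frame(marker1 = "m2", marker2 = "m5",
                      h2_aa = 0.02, h2_aae = 0)
  cfg <- sim_config(map, qts, pairs, n_genotypes = 500L,
                    environments = 3L, reps_per_env = 1L,
                    total_h2 = 0.0933, phenotypic_variance = 100)
  g <- simulate_ril_genotypes(map, 500L, seed = 5)
  tr <- calibrate_effects(cfg, g)
  expect_equal(abs(tr$a[["m2"]]), sqrt(2.33), tolerance = 1e-10)
  expect_equal(tr$a[["m8"]], 0)  # zero heritability, zero effect
  pv <- var(g$values[, "m2"] * g$values[, "m5"])
  expect_equal(abs(tr$aa[1]), sqrt(2 / pv), tolerance = 1e-10)
  expect_equal(tr$sigma2_res, 100 * (1 - 0.0933))
  # GxE rows sum to zero with the calibrated mean square
  cfg2 <- sim_config(map, transform(qts, h2_ae = c(0.01, 0, 0)), pairs,
                     total_h2 = 0.1033, reps_per_env = 1L)
  tr2 <- calibrate_effects(cfg2, g)
  expect_equal(sum(tr2$ae[1, ]), 0, tolerance = 1e-10)
  expect_equal(mean(tr2$ae[1, ]^2), 0.01 * 100, tolerance = 1e-10)
})

test_that("heritability budgets are validated", {
  map <- h_map()
  qts <- data.frame(marker = "m1", h2_a = 0.1, h2_ae = 0)
  expect_error(sim_config(map, qts, total_h2 = 0.2), "sum to")
  expect_error(sim_config(map, data.frame(marker = "nope", h2_a = 0.2,
                                          h2_ae = 0), total_h2 = 0.2),
               "not on map")
})

test_that("phenotypes reduce to mean plus environment when all effects vanish", {
  map <- h_map()
  qts <- data.frame(marker = "m1", h2_a = 0, h2_ae = 0)
  cfg <- sim_config(map, qts, total_h2 = 0, phenotypic_variance = 100,
                    n_genotypes = 20L, reps_per_env = 1L)
  g <- simulate_ril_genotypes(map, 20L, seed = 3)
  tr <- calibrate_effects(cfg, g)
  tr$sigma2_res <- 0
  ph <- simulate_phenotypes(cfg, g, tr, seed = 4)
  expect_equal(ph$value,
               cfg$mu + cfg$env_effects[as.integer(factor(ph$environment))])
})

test_that("phenotype simulation is reproducible and regression recovers effects", {
  map <- h_map(chr = 5L, m = 3L, spacing = 40)
  qts <- data.frame(marker = c("m2", "m5"), h2_a = c(0.08, 0.06),
                    h2_ae = c(0, 0))
  cfg <- sim_config(map, qts, total_h2 = 0.14, n_genotypes = 300L,
                    reps_per_env = 2L, seed = 2)
  g <- simulate_ril_genotypes(map, 300L, seed = 6)
  tr <- calibrate_effects(cfg, g)
  p1 <- simulate_phenotypes(cfg, g, tr, seed = 8)
  p2 <- simulate_phenotypes(cfg, g, tr, seed = 8)
  expect_identical(p1$value, p2$value)
  ridx <- match(p1$individual, rownames(g$values))
  fit <- lm(p1$value ~ g$values[ridx, "m2"] + factor(p1$environment))
  co <- summary(fit)$coefficients
  expect_lt(abs(co[2, 1] - tr$a[["m2"]]), 2 * co[2, 2])
})

test_that("realized heritability tracks the configured total", {
  # reduced marker panel carrying the full default architecture
  map <- genetic_map(sprintf("c%02dm058", 1:5), sprintf("chr%02d", 1:5),
                     rep(50, 5))
  cfg <- qts_sim_config(map = map)
  h2 <- replicate(50, {
    s <- sample.int(1e6, 2)
    g <- simulate_ril_genotypes(map, cfg$n_genotypes, seed = s[1])
    tr <- calibrate_effects(cfg, g)
    realized_h2(simulate_phenotypes(cfg, g, tr, seed = s[2]))
  })
  expect_lt(abs(mean(h2) - 0.20), 0.02)
})

test_that("expression populations are standardized and reproducible", {
  map <- h_map(chr = 4L, m = 3L, spacing = 30)
  qts <- data.frame(marker = c("m2", "m5", "m8", "m11"),
                    h2_a = c(2.5, 2.0, 3.0, 1.5) / 100,
                    h2_ae = rep(0.25, 4) / 100)
  pairs <- data.frame(marker1 = c("m2", "m2", "m8"),
                      marker2 = c("m8", "m11", "m11"),
                      h2_aa = rep(3, 3) / 100, h2_aae = rep(1 / 3, 3) / 100)
  cfg <- sim_config(map, qts, pairs, mode = "qtt")
  g1 <- simulate_expression_population(cfg, seed = 9)
  g2 <- simulate_expression_population(cfg, seed = 9)
  expect_identical(g1$values, g2$values)
  expect_equal(g1$mode, "continuous")
  expect_equal(unname(colMeans(g1$values)), rep(0, ncol(g1$values)),
               tolerance = 1e-12)
  expect_equal(unname(apply(g1$values, 2, sd)), rep(1, ncol(g1$values)),
               tolerance = 1e-12)
})
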