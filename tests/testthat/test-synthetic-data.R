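# Generator contracts: determinism, coding, calibration of variances /
# correlation / major-locus fraction, trial bookkeeping.

smallCfg <- function(...) {
  args <- list(n_lines = 120, n_families = 75, markers_per_chromosome = 10,
               missing_rate = 0, seed = 1)
  args[names(list(...))] <- list(...)
  do.call(simConfig, args)
}

test_that("config validation rejects out-of-range settings", {
  expect_error(simConfig(n_lines = 10, n_families = 20), "n_families")
  expect_error(simConfig(major_qtl_rho = 1.2), "fractions")
  expect_error(simConfig(maf_range = c(0.3, 0.1)), "maf_range")
  expect_error(simConfig(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simConfig(genetic_correlation = 1.5), "genetic_correlation")
})

test_that("same seed gives a bit-identical population", {
  p1 <- simulatePopulation(smallCfg(seed = 42, missing_rate = 0.05))
  p2 <- simulatePopulation(smallCfg(seed = 42, missing_rate = 0.05))
  expect_identical(genoCodes(genotypes(p1)), genoCodes(genotypes(p2)))
  expect_identical(trueBreedingValues(p1), trueBreedingValues(p2))
  expect_identical(p1@cnvState, p2@cnvState)
})

test_that("genotype codes, founder frequencies and missingness meet contract", {
  cfg <- smallCfg(n_lines = 300, n_families = 180, markers_per_chromosome = 20,
                  missing_rate = 0.05, seed = 3)
  pop <- simulatePopulation(cfg)
  cd <- genoCodes(genotypes(pop))
  expect_true(all(cd %in% c(-1, 0, 1) | is.na(cd)))
  f <- pop@varianceTruth$founderFreq
  expect_true(all(pmin(f, 1 - f) >= cfg$maf_range[1] - 1e-9))
  # >= 1e5 calls: injected missingness within 1 percentage point
  expect_gt(length(cd), 1e5)
  expect_lt(abs(mean(is.na(cd)) - 0.05), 0.01)
})

test_that("TBV calibration is exact: variances, correlation, major fraction", {
  pop <- simulatePopulation(smallCfg(seed = 5))
  tbv <- trueBreedingValues(pop)
  sG2 <- pop@varianceTruth$sigma2G
  expect_equal(unname(apply(tbv, 2, var)), unname(sG2), tolerance = 1e-10)
  expect_equal(cor(tbv)[1, 2], 0.6, tolerance = 1e-10)
  # regression of TBV on the causal copy-number state recovers rho
  r2 <- summary(lm(tbv[, "frost"] ~ factor(pop@cnvState)))$r.squared
  expect_equal(r2, 0.20, tolerance = 0.02)
})

test_that("TBV variance hits sigma2G at large n as well", {
  pop <- simulatePopulation(simConfig(n_lines = 2000, n_families = 1200,
                                      markers_per_chromosome = 5,
                                      missing_rate = 0, seed = 8))
  expect_equal(var(trueBreedingValues(pop)[, "winter"]),
               unname(pop@varianceTruth$sigma2G["winter"]), tolerance = 0.05)
})

test_that("perfect genetic correlation makes the two TBVs proportional", {
  pop <- simulatePopulation(smallCfg(genetic_correlation = 1, seed = 6))
  tbv <- trueBreedingValues(pop)
  expect_equal(cor(tbv[, 1], tbv[, 2]), 1, tolerance = 1e-10)
})

test_that("without a planted major locus the haploblock explains ~nothing", {
  r2 <- vapply(1:20, function(s) {
    pop <- simulatePopulation(smallCfg(major_qtl_rho = 0, seed = 200 + s))
    tags <- pop@majorLocus$tags
    hb <- buildHaploblock(genotypes(pop), tags[1], tags[2])
    summary(lm(trueBreedingValues(pop)[, "frost"] ~ blockCodes(hb)))$r.squared
  }, 0)
  expect_lt(mean(r2), 0.05)
})

test_that("paper-scale generator puts the haploblock R2 in the target band", {
  r2 <- vapply(1:12, function(s) {
    pop <- simulatePopulation(simConfig(missing_rate = 0, seed = 300 + s))
    tags <- pop@majorLocus$tags
    hb <- buildHaploblock(genotypes(pop), tags[1], tags[2])
    summary(lm(trueBreedingValues(pop)[, "frost"] ~ blockCodes(hb)))$r.squared
  }, 0)
  expect_gte(mean(r2), 0.12)
  expect_lte(mean(r2), 0.28)
})

test_that("field trial bookkeeping: replication counts and design labels", {
  pop <- simulatePopulation(smallCfg(seed = 7))
  ft <- simulateFieldTrial(pop, "winter", n_replicated = 120,
                           n_unreplicated = 0, seed = 1)
  expect_equal(nrow(ft), 240)
  expect_true(all(table(ft$line) == 2))
  expect_true(all(c("line", "trial", "block", "row", "column", "trait",
                    "value") %in% names(ft)))
  ft2 <- simulateFieldTrial(pop, "winter", 40, 60, seed = 2)
  expect_equal(nrow(ft2), 140)
  expect_equal(sum(table(ft2$line) == 2), 40)
  expect_equal(sum(table(ft2$line) == 1), 60)
  expect_true(all(ft2$value >= 1 & ft2$value <= 9))
})

test_that("noise-free frost limit returns TBV plus block effect exactly", {
  pop <- simulatePopulation(smallCfg(seed = 9))
  fr <- simulateFrostExperiment(pop, 3, seed = 4, h2 = 1)
  tbv <- trueBreedingValues(pop)[, "frost"]
  byBlock <- split(fr, fr$block)
  for (bl in byBlock) {
    resid <- bl$value - tbv[bl$line]
    # constant within block (block effect + grand mean), unless truncated
    inRange <- bl$value > 0 & bl$value < 100
    expect_lt(diff(range(resid[inRange])), 1e-10)
  }
})

test_that("frost experiment is a complete block design on the 0-100 scale", {
  pop <- simulatePopulation(simConfig(n_lines = 213, n_families = 140,
                                      markers_per_chromosome = 5,
                                      missing_rate = 0, seed = 10))
  fr <- simulateFrostExperiment(pop, 4, seed = 5)
  expect_equal(nrow(fr), 852)
  expect_true(all(table(fr$line, fr$block) == 1))
  expect_true(all(fr$value >= 0 & fr$value <= 100))
  expect_error(simulateFrostExperiment(pop, 1, seed = 1), "n_blocks")
})

test_that("trial simulators reject oversized entry lists", {
  pop <- simulatePopulation(smallCfg(seed = 11))
  expect_error(simulateFieldTrial(pop, "winter", 100, 100, seed = 1),
               "exceeds")
})

test_that("genotype writer and reader round-trip", {
  pop <- simulatePopulation(smallCfg(n_lines = 30, n_families = 20,
                                     markers_per_chromosome = 4,
                                     missing_rate = 0.05, seed = 12))
  pre <- file.path(tempdir(), "rt")
  writeGenotypes(genotypes(pop), pre)
  g2 <- readGenotypes(pre)
  expect_equal(genoCodes(g2), genoCodes(genotypes(pop)))
  expect_equal(markerMap(g2)$chrom, markerMap(genotypes(pop))$chrom)
  ph <- simulateFieldTrial(pop, "winter", 10, 10, seed = 3)
  fp <- file.path(tempdir(), "ph.csv")
  writePhenotypes(ph, fp)
  expect_equal(readPhenotypes(fp)$value, ph$value)
})
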