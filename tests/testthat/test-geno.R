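# Genotype curation micro-oracles: hand-counted QC, kNN imputation,
# haploblock truth table, VanRaden GRM worked example, kinship PCA.

test_that("QC removes exactly the hand-counted markers on a 10-line fixture", {
  codes <- cbind(
    ok      = c(1, 1, -1, -1, 1, -1, 1, -1, 1, -1),   # maf 0.5
    rareMin = c(0, rep(1, 9)),   # a single minor allele (one het): maf 0.05
    miss20  = c(NA, NA, 1, -1, 1, -1, 1, -1, 1, -1),  # 20% missing
    miss10  = c(NA, 1, 1, -1, 1, -1, 1, -1, 1, -1))   # exactly 10%: kept
  g <- toyGeno(codes)
  out <- qcFilter(g)
  expect_setequal(markerIds(out$geno), c("ok", "miss10"))
  expect_setequal(out$report$marker, c("rareMin", "miss20"))
  expect_equal(out$report$reason[out$report$marker == "rareMin"], "maf")
  expect_equal(out$report$reason[out$report$marker == "miss20"], "missing")
  # already-clean matrix passes through unchanged with an empty report
  clean <- qcFilter(out$geno)
  expect_identical(genoCodes(clean$geno), genoCodes(out$geno))
  expect_equal(nrow(clean$report), 0)
  expect_error(qcFilter(toyGeno(cbind(m = rep(1, 10)))), "every marker")
})

test_that("imputation is an identity on complete data and copies duplicates", {
  g <- predFixture()$geno
  expect_identical(genoCodes(imputeGenotypes(g)), genoCodes(g))
  # a line duplicating another on the chromosome gets the duplicate's value
  codes <- rbind(a = c(1, -1, 1, -1, 1), b = c(1, -1, 1, -1, 1),
                 c = c(-1, 1, -1, 1, -1), d = c(-1, 1, 1, 1, -1))
  colnames(codes) <- paste0("m", 1:5)
  codes["b", 3] <- NA
  gi <- imputeGenotypes(toyGeno(codes))
  expect_equal(genoCodes(gi)["b", 3], 1)
  expect_equal(genoCodes(gi)[-2, ], codes[-2, ])  # observed entries untouched
})

test_that("mask-and-recover imputation error stays below 15%", {
  pop <- simulatePopulation(simConfig(n_lines = 300, n_families = 180,
                                      n_chromosomes = 6, n_qtl = 30,
                                      markers_per_chromosome = 67,
                                      missing_rate = 0, seed = 77))
  truth <- pop@truthCodes
  errs <- vapply(1:20, function(s) {
    set.seed(400 + s)
    obs <- truth
    mask <- matrix(runif(length(obs)) < 0.05, nrow(obs))
    obs[mask] <- NA
    g <- GenotypeData(obs, markerMap(genotypes(pop)))
    imp <- genoCodes(imputeGenotypes(g))
    mean(imp[mask] != truth[mask])
  }, 0)
  expect_lt(mean(errs), 0.15)
})

test_that("haploblock coding follows the exact truth table", {
  combos <- expand.grid(a = c(-1, 0, 1), b = c(-1, 0, 1))
  codes <- cbind(A = combos$a, B = combos$b, filler = rep(c(1, -1, 1), 3))
  g <- toyGeno(codes)
  hb <- buildHaploblock(g, "A", "B", favorable = c(1, 1), name = "t")
  expected <- ifelse(combos$a == 1 & combos$b == 1, 1,
                     ifelse(combos$a == -1 & combos$b == -1, -1, 0))
  expect_equal(unname(blockCodes(hb)), expected)
  # favorable allele orientation flips the homozygous classes
  hbF <- buildHaploblock(g, "A", "B", favorable = c(-1, -1), name = "t")
  expect_equal(unname(blockCodes(hbF)), -expected)
  expect_error(buildHaploblock(g, "A", "nope"), "unknown marker")
})

test_that("GRM reproduces the two-line worked example and its invariants", {
  g <- toyGeno(matrix(c(1, -1), 2, 1))
  K <- computeGRM(g)
  expect_equal(unname(K), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  # identical lines: diagonal equals off-diagonal
  g2 <- toyGeno(rbind(a = c(1, -1, 1, 1), b = c(1, -1, 1, 1),
                      c = c(-1, 1, -1, 1)))
  K2 <- computeGRM(g2)
  expect_equal(K2["a", "a"], K2["a", "b"], tolerance = 1e-12)
  expect_lt(max(abs(rowSums(K2))), 1e-8)
  # monomorphic marker leaves K unchanged; permutation equivariance
  fx <- predFixture()
  gsub <- fx$geno[1:40, 1:60]
  Ka <- computeGRM(gsub)
  codesMono <- cbind(genoCodes(gsub), mono = rep(1, 40))
  gMono <- toyGeno(codesMono)
  expect_equal(unname(computeGRM(gMono)), unname(Ka), tolerance = 1e-10)
  perm <- sample(60)
  expect_equal(unname(computeGRM(gsub[, perm])), unname(Ka), tolerance = 1e-10)
  expect_error(computeGRM(toyGeno(cbind(m = c(1, 1, 1)))), "monomorphic")
})

test_that("perfect-LD dedup keeps one representative per clique", {
  set.seed(1)
  base <- matrix(sample(c(-1, 1), 30 * 4, replace = TRUE), 30, 4)
  colnames(base) <- paste0("m", 1:4)
  codes <- cbind(base, dupA = base[, 1], flipB = -base[, 2],
                 mono = rep(1, 30))
  g <- toyGeno(codes)
  out <- dedupPerfectLD(g, seed = 3)
  expect_equal(sum(out$dropped$reason == "monomorphic"), 1)
  # one of each perfect pair dropped; survivors have no r2 = 1 pair left
  cm <- cor(genoCodes(out$geno))
  expect_lt(max(cm[upper.tri(cm)]^2), 1 - 1e-12)
  expect_true(xor("m1" %in% markerIds(out$geno), "dupA" %in% markerIds(out$geno)))
  # seeded determinism
  out2 <- dedupPerfectLD(g, seed = 3)
  expect_identical(markerIds(out$geno), markerIds(out2$geno))
  expect_error(dedupPerfectLD(toyGeno(cbind(m = c(1, NA, -1)))), "complete")
})

test_that("curation pipeline is idempotent on a second pass", {
  fx <- predFixture()
  qc2 <- qcFilter(fx$geno)
  expect_equal(nrow(qc2$report), 0)
  g2 <- dedupPerfectLD(imputeGenotypes(qc2$geno), seed = 1)$geno
  expect_identical(genoCodes(g2), genoCodes(fx$geno))
})

test_that("kinship PCA separates diverged families and sums variance to 1", {
  pc <- kinshipPCA(predFixture()$K, 3)
  expect_equal(sum(pc$varFrac), 1, tolerance = 1e-10)
  expect_error(kinshipPCA(predFixture()$K, 10000), "exceeds")
  # two diverged groups built from opposite founder blocks
  seps <- vapply(1:20, function(s) {
    set.seed(500 + s)
    n <- 60; m <- 120
    common <- matrix(sample(c(-1, 1), m, TRUE), 1, m)
    grpA <- matrix(sample(c(-1, 1), m, TRUE), 1, m)
    noise <- function(k) matrix(sample(c(-1, 1), k * m, TRUE, prob = c(.15, .85)), k, m)
    codes <- rbind(common[rep(1, n / 2), ] * noise(n / 2),
                   grpA[rep(1, n / 2), ] * noise(n / 2))
    rownames(codes) <- paste0("L", 1:n)
    K <- computeGRM(toyGeno(codes))
    sc <- kinshipPCA(K, 1)$scores[, 1]
    abs(cor(sc, rep(c(0, 1), each = n / 2)))
  }, 0)
  expect_true(all(seps > 0.8))
  # degenerate: identical lines -> single trivial eigenvalue
  Kid <- computeGRM(toyGeno(rbind(a = c(1, -1, 1), b = c(1, -1, 1),
                                  c = c(-1, 1, -1), d = c(-1, 1, -1))))
  ev <- kinshipPCA(Kid, 2)$values
  expect_lt(abs(ev[2]), 1e-8)
})
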