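# GBLUP / WBLUP / RR-BLUP predictions against dense closed forms, the
# GBLUP-RRBLUP duality, the kinship-corrected association scan, and the
# locus variance-explained estimator.

test_that("GBLUP equals the dense GLS oracle on a mid-sized instance", {
  fx <- predFixture()
  train <- names(fx$blues)[1:130]
  val <- names(fx$blues)[131:160]
  pred <- gblupPredict(fx$blues[train], fx$K, val)
  fit <- attr(pred, "fit")
  Ktt <- fx$K[train, train]
  V <- fit$vc["g"] * Ktt + fit$vc["residual"] * diag(130)
  Vi <- solve(V)
  X <- matrix(1, 130, 1)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% fx$blues[train])
  uo <- as.numeric(fit$vc["g"] * fx$K[val, train] %*% Vi %*%
                     (fx$blues[train] - as.numeric(b)))
  expect_equal(unname(pred$value), as.numeric(b) + uo, tolerance = 1e-8)
})

test_that("validation lines unrelated to training get the intercept only", {
  set.seed(2)
  n <- 30
  K <- diag(0.5, n + 1)
  K[1:n, 1:n] <- K[1:n, 1:n] + 0.5
  dimnames(K) <- list(paste0("L", 1:(n + 1)), paste0("L", 1:(n + 1)))
  y <- setNames(rnorm(n, 7), paste0("L", 1:n))
  pred <- gblupPredict(y, K, paste0("L", n + 1))
  fit <- attr(pred, "fit")
  expect_equal(unname(pred$value), unname(fit$beta[1]), tolerance = 1e-8)
})

test_that("a duplicate of a training line inherits that line's prediction", {
  fx <- predFixture()
  train <- names(fx$blues)[1:100]
  K <- fx$K
  dup <- "DUP"
  K2 <- rbind(cbind(K, K[, train[1], drop = FALSE]),
              c(K[train[1], ], K[train[1], train[1]]))
  rownames(K2)[nrow(K2)] <- dup; colnames(K2)[ncol(K2)] <- dup
  pred <- gblupPredict(fx$blues[train], K2, c(train[1], dup))
  expect_equal(pred$value[1], pred$value[2], tolerance = 1e-8)
  expect_error(gblupPredict(fx$blues[train], K, "missing_line"), "absent")
})

test_that("GBLUP and RR-BLUP are dual on the same marker set", {
  fx <- predFixture()
  train <- names(fx$blues)[1:130]
  val <- names(fx$blues)[131:160]
  pg <- gblupPredict(fx$blues[train], fx$K, val)
  pr <- rrblupPredict(fx$blues[train], fx$geno, validationLines = val)$gebv
  expect_equal(pg$value, pr$value, tolerance = 1e-6)
})

test_that("single-marker RR-BLUP is a shrunken simple regression", {
  set.seed(4)
  n <- 60
  m <- sample(c(-1, 1), n, TRUE)
  y <- setNames(1 + 0.8 * m + rnorm(n, 0, 0.6), paste0("L", 1:n))
  g <- toyGeno(matrix(m, n, 1, dimnames = list(names(y), "mk")))
  out <- rrblupPredict(y, g, "mk", validationLines = names(y)[1:3])
  fit <- attr(out$gebv, "fit")
  lam <- fit$vc["residual"] / fit$vc["m"]
  mc <- m - mean(m) * 0  # raw codes enter Z directly
  # closed form: intercept + shrunken slope from the mixed-model equations
  mm <- solveMME(unname(y), NULL, list(m = list(Z = matrix(m, n, 1), K = NULL)),
                 fit$vc)
  expect_equal(out$markerEffects$effect, unname(mm$u$m), tolerance = 1e-6)
  expect_lt(abs(out$markerEffects$effect), abs(coef(lm(y ~ m))[2]))
})

test_that("WBLUP requires a polymorphic haploblock and uses its fixed effect", {
  fx <- predFixture()
  train <- names(fx$blues)[1:130]
  val <- names(fx$blues)[131:160]
  pw <- wblupPredict(fx$blues[train], fx$K, fx$hb, val)
  fit <- attr(pw, "fit")
  # favorable haploblock alleles lower the frost damage
  expect_lt(fit$beta["hb"], 0)
  constHb <- new("Haploblock", name = "const", markerA = "a", markerB = "b",
                 favorable = c(a = 1, b = 1),
                 codes = setNames(rep(1, nrow(fx$K)), rownames(fx$K)))
  expect_error(wblupPredict(fx$blues[train], fx$K, constHb, val),
               "monomorphic")
})

test_that("predictions are invariant to a constant shift of training BLUEs", {
  fx <- predFixture()
  train <- names(fx$blues)[1:120]
  val <- names(fx$blues)[121:160]
  p1 <- gblupPredict(fx$blues[train], fx$K, val)
  p2 <- gblupPredict(fx$blues[train] + 50, fx$K, val)
  expect_equal(p2$value - 50, p1$value, tolerance = 1e-6)
})

test_that("association scan flags monomorphic markers and finds the planted locus", {
  fx <- predFixture()
  train <- names(fx$blues)[1:130]
  codes <- genoCodes(fx$geno)
  codes <- cbind(codes, mono = rep(1, nrow(codes)))
  gmono <- toyGeno(codes, chrom = c(markerMap(fx$geno)$chrom, 21))
  gw <- gwasScan(fx$blues[train], gmono, fx$K)
  expect_equal(gw$p[gw$marker == "mono"], 1)
  expect_equal(gw$flag[gw$marker == "mono"], "monomorphic")
  expect_true(all(gw$p > 0 & gw$p <= 1))
  # planted major locus: smallest p lands on a tag marker in most seeds
  hits <- vapply(1:25, function(s) {
    pop <- simulatePopulation(simConfig(n_lines = 130, n_families = 80,
                                        markers_per_chromosome = 15,
                                        missing_rate = 0, seed = 900 + s))
    g <- genotypes(pop)
    K <- computeGRM(g)
    y <- setNames(trueBreedingValues(pop)[, "frost"], lineIds(g)) +
      rnorm(130, 0, 0.2 * sqrt(pop@varianceTruth$sigma2G["frost"]))
    gw <- gwasScan(y, g, K)
    gw$marker[which.min(gw$p)] %in% pop@majorLocus$tags
  }, NA)
  expect_gte(sum(hits), 18)
})

test_that("null phenotypes give calibrated association p-values", {
  fx <- predFixture()
  ksOK <- vapply(1:8, function(s) {
    set.seed(1000 + s)
    y <- setNames(rnorm(130), names(fx$blues)[1:130])
    gw <- gwasScan(y, fx$geno, fx$K)
    suppressWarnings(ks.test(gw$p[gw$flag == ""], "punif")$p.value) > 0.01
  }, NA)
  expect_gte(sum(ksOK), 6)
})

test_that("variance explained is ~0 for null loci and ~1 for a saturated locus", {
  fx <- predFixture()
  train <- names(fx$blues)[1:130]
  rhoNull <- vapply(1:10, function(s) {
    set.seed(1100 + s)
    fake <- setNames(sample(c(-1, 0, 1), nrow(fx$K), TRUE,
                            prob = c(.4, .2, .4)), rownames(fx$K))
    varianceExplained(fx$blues[train], fx$K, fake)$rhoG
  }, 0)
  expect_lt(mean(rhoNull), 0.03)
  # a locus that IS the genetic signal absorbs essentially all of sigma2G
  set.seed(5)
  mk <- markerIds(fx$geno)[40]
  locus <- setNames(genoCodes(fx$geno)[, mk], lineIds(fx$geno))
  ySat <- setNames(2 * locus[train] + rnorm(130, 0, 0.3), train)
  ve <- varianceExplained(ySat, fx$K, locus)
  expect_gt(ve$rhoG, 0.8)
  expect_error(varianceExplained(fx$blues[train], fx$K,
                                 setNames(rep(1, nrow(fx$K)), rownames(fx$K))),
               "monomorphic")
})
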