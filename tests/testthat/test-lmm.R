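# REML engine against closed-form and dense-matrix oracles.

simOneWay <- function(g, r, s2g = 4, s2e = 1, seed = 1) {
  set.seed(seed)
  grp <- factor(rep(seq_len(g), each = r))
  y <- rnorm(g, 0, sqrt(s2g))[grp] + rnorm(g * r, 0, sqrt(s2e))
  list(y = y, grp = grp, Z = model.matrix(~ 0 + grp))
}

test_that("balanced one-way REML matches the ANOVA variance estimator", {
  for (seed in 1:3) {
    d <- simOneWay(15, 4, seed = seed)
    fit <- fitREML(d$y, NULL, list(grp = list(Z = d$Z, K = NULL)))
    ms <- anova(lm(d$y ~ d$grp))$`Mean Sq`
    s2gAnova <- (ms[1] - ms[2]) / 4
    expect_gt(s2gAnova, 0)  # interior optimum by construction (s2g >> s2e/r)
    expect_equal(unname(fit$vc["grp"]), s2gAnova, tolerance = 1e-6)
    expect_equal(unname(fit$vc["residual"]), ms[2], tolerance = 1e-6)
  }
})

test_that("noise-free response drives all variance components to the boundary", {
  X <- cbind(1, rep(c(0, 1), each = 10))
  colnames(X) <- c("int", "trt")
  y <- as.numeric(X %*% c(2, 3))
  fit <- fitREML(y, X, list(g = list(Z = NULL, K = diag(20))))
  expect_equal(unname(fit$vc), c(0, 0))
  expect_equal(unname(fit$beta), c(2, 3))
  expect_true(all(fit$boundary))
})

test_that("spectral and direct REML routes agree on a kernel model", {
  set.seed(11)
  n <- 40
  K <- tcrossprod(matrix(rnorm(n * 30), n, 30)) / 30
  y <- as.numeric(t(chol(K + 1e-8 * diag(n))) %*% rnorm(n)) + rnorm(n, 0, 0.8)
  f1 <- fitREML(y, NULL, list(g = K), method = "spectral")
  f2 <- fitREML(y, NULL, list(g = K), method = "direct")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$vc, f2$vc, tolerance = 1e-3)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-4)
})

test_that("solveMME reproduces the dense GLS closed form on random instances", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    q <- sample(10:40, 1)
    K <- tcrossprod(matrix(rnorm(n * q), n, q)) / q
    X <- cbind(1, rnorm(n))
    colnames(X) <- c("int", "x")
    y <- rnorm(n, 1, 2)
    vc <- c(g = runif(1, 0.2, 3), residual = runif(1, 0.2, 3))
    mme <- solveMME(y, X, list(g = K), vc)
    V <- vc["g"] * K + vc["residual"] * diag(n)
    Vi <- solve(V)
    bOracle <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    uOracle <- as.numeric(vc["g"] * K %*% Vi %*% (y - X %*% bOracle))
    expect_equal(unname(mme$beta), as.numeric(bOracle), tolerance = 1e-8)
    expect_equal(unname(mme$u$g), uOracle, tolerance = 1e-8)
  }
})

test_that("solveMME reproduces fitREML's internal solutions at the optimum", {
  set.seed(21)
  n <- 35
  K <- tcrossprod(matrix(rnorm(n * 25), n, 25)) / 25
  y <- as.numeric(t(chol(K + 1e-8 * diag(n))) %*% rnorm(n)) + rnorm(n)
  fit <- fitREML(y, NULL, list(g = K))
  mme <- solveMME(y, NULL, list(g = K), fit$vc)
  expect_equal(unname(mme$beta), unname(fit$beta), tolerance = 1e-8)
  expect_equal(unname(mme$u$g), unname(fit$blups$g), tolerance = 1e-8)
})

test_that("identity-kernel BLUPs follow the scalar shrinkage closed form", {
  set.seed(3)
  n <- 30
  y <- rnorm(n, 5, 2)
  vc <- c(g = 1.5, residual = 0.5)
  mme <- solveMME(y, NULL, list(g = diag(n)), vc)
  shrink <- vc["g"] / (vc["g"] + vc["residual"])
  expect_equal(unname(mme$u$g), unname(shrink * (y - mean(y))),
               tolerance = 1e-10)
  # infinite-shrinkage limit: variance ratio -> 0 kills all BLUPs
  mme0 <- solveMME(y, NULL, list(g = diag(n)), c(g = 1e-10, residual = 1))
  expect_lt(max(abs(mme0$u$g)), 1e-8)
})

test_that("REML is invariant to row reordering and scales quadratically", {
  set.seed(7)
  n <- 30
  K <- tcrossprod(matrix(rnorm(n * 20), n, 20)) / 20
  y <- as.numeric(t(chol(K + 1e-8 * diag(n))) %*% rnorm(n)) + rnorm(n)
  f <- fitREML(y, NULL, list(g = K))
  perm <- sample(n)
  fp <- fitREML(y[perm], NULL, list(g = K[perm, perm]))
  expect_equal(f$vc, fp$vc, tolerance = 1e-6)
  f2 <- fitREML(2 * y, NULL, list(g = K))
  expect_equal(unname(f2$vc), unname(4 * f$vc), tolerance = 1e-5)
  expect_equal(f2$vc["g"] / sum(f2$vc), f$vc["g"] / sum(f$vc),
               tolerance = 1e-6)
})

test_that("singular fixed designs raise an error naming the aliased column", {
  X <- cbind(int = 1, a = rep(1:0, 10), b = rep(1:0, 10))
  y <- rnorm(20)
  expect_error(fitREML(y, X, list(g = diag(20))), "aliased.*b")
})

test_that("non-symmetric or indefinite kernels are rejected", {
  y <- rnorm(12)
  Kbad <- matrix(rnorm(144), 12, 12)
  expect_error(fitREML(y, NULL, list(g = Kbad)), "symmetric")
  Kneg <- diag(12); Kneg[1, 1] <- -2
  expect_error(fitREML(y, NULL, list(g = Kneg)), "semidefinite")
})

test_that("AIC is reproducible and guarded against mismatched fixed parts", {
  d <- simOneWay(10, 3, seed = 2)
  f1 <- fitREML(d$y, NULL, list(grp = list(Z = d$Z, K = NULL)))
  f2 <- fitREML(d$y, NULL, list(grp = list(Z = d$Z, K = NULL)))
  expect_identical(f1$aic, f2$aic)
  X2 <- cbind(1, rnorm(length(d$y)))
  f3 <- fitREML(d$y, X2, list(grp = list(Z = d$Z, K = NULL)))
  expect_error(compareAIC(f1, f3), "identical fixed designs")
})

test_that("AIC selects the data-generating random structure", {
  winsTrue <- 0; okNull <- 0
  nSeeds <- 50
  for (seed in seq_len(nSeeds)) {
    set.seed(100 + seed)
    g <- 12; r <- 3
    grp <- factor(rep(seq_len(g), each = r))
    Z <- model.matrix(~ 0 + grp)
    # strong group signal: model with the generating term should win
    y <- rnorm(g, 0, 3)[grp] + rnorm(g * r)
    fWith <- fitREML(y, NULL, list(grp = list(Z = Z, K = NULL)))
    fWithout <- fitREML(y, NULL, list())
    if (fWith$aic < fWithout$aic) winsTrue <- winsTrue + 1
    # null data: the extra term should not be rewarded beyond noise
    y0 <- rnorm(g * r)
    aWith <- fitREML(y0, NULL, list(grp = list(Z = Z, K = NULL)))$aic
    aWithout <- fitREML(y0, NULL, list())$aic
    if (aWith >= aWithout - 1e-6) okNull <- okNull + 1
  }
  expect_gte(winsTrue, 45)
  expect_gt(okNull, nSeeds / 2)
})
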