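# REML engine shared by the phenotypic analysis, GBLUP/WBLUP, RR-BLUP and the
# association scan. Two routes are provided:
#   * spectral: profiled restricted likelihood for models with a single random
#     term (one eigendecomposition, then 1-D optimisation over the variance
#     ratio) -- the hot path used by genomic prediction and GWAS;
#   * direct: generic optimisation over all log-variances, with each
#     likelihood evaluation reduced to q x q linear algebra via the Woodbury
#     identity on the low-rank random-effect structure.

# normalize a random-term specification to list(Z=, K=, U=) where
# V = s2r I + sum_k s2k Z_k K_k Z_k' and U_k is a factor with Z K Z' = U U'
normalizeRandom <- function(random, n) {
  if (length(random) == 0) return(list())
  if (is.null(names(random)) || any(names(random) == ""))
    names(random) <- paste0("u", seq_along(random))
  lapply(random, function(term) {
    if (is.matrix(term)) term <- list(Z = NULL, K = term)
    Z <- term$Z; K <- term$K
    if (!is.null(Z)) {
      Z <- as.matrix(Z)
      if (nrow(Z) != n) stop("random-term design matrix must have ", n, " rows")
    }
    q <- if (is.null(Z)) n else ncol(Z)
    if (!is.null(K)) {
      K <- as.matrix(K)
      if (nrow(K) != q || ncol(K) != q)
        stop("kernel dimension does not match its design matrix")
      if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
        stop("covariance kernel is not symmetric")
      ek <- eigen(K, symmetric = TRUE)
      if (min(ek$values) < -1e-6 * max(abs(ek$values), 1))
        stop("covariance kernel is not positive semidefinite")
      keep <- ek$values > max(ek$values, 0) * 1e-12
      G <- ek$vectors[, keep, drop = FALSE] %*%
        diag(sqrt(ek$values[keep]), sum(keep))
      U <- if (is.null(Z)) G else Z %*% G
    } else {
      U <- if (is.null(Z)) diag(n) else Z
    }
    list(Z = Z, K = K, U = U)
  })
}

checkFixedRank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed design is singular; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  qrX
}

xSignature <- function(X) {
  paste(nrow(X), ncol(X), paste(colnames(X), collapse = "|"),
        format(sum(abs(X)), digits = 12), sep = ";")
}

#' Fit a linear mixed model by REML
#'
#' Restricted maximum likelihood for \eqn{y = X\beta + \sum_k Z_k u_k + r}
#' with \eqn{u_k \sim N(0, K_k \sigma^2_k)} and \eqn{r \sim N(0, I\sigma^2_r)}.
#' Variance components are constrained non-negative (log-scale optimisation);
#' estimates hitting the boundary are flagged. Fixed effects are estimated by
#' GLS at the REML optimum and random effects by BLUP.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (defaults to an intercept). Must be
#'   full column rank; aliased columns raise an error naming them.
#' @param random named list of random terms. Each term is either a square
#'   covariance kernel \code{K} (design taken as identity) or a list with
#'   elements \code{Z} (design matrix, \code{NULL} for identity) and \code{K}
#'   (kernel, \code{NULL} for identity).
#' @param method \code{"spectral"} (single random term only), \code{"direct"},
#'   or \code{"auto"} (spectral when a single term, direct otherwise).
#' @param tol relative convergence tolerance on the restricted log-likelihood.
#' @param maxIter iteration cap for the direct optimiser.
#' @return An object of class \code{remlFit}: list with \code{vc} (named
#'   variance components including \code{residual}), \code{loglik} (restricted
#'   log-likelihood), \code{aic}, \code{beta}, \code{betaCov}, \code{blups}
#'   (named list), \code{fitted}, \code{converged}, \code{boundary} flags.
#' @export
fitREML <- function(y, X = NULL, random = list(),
                    method = c("auto", "spectral", "direct"),
                    tol = 1e-8, maxIter = 200) {
  method <- match.arg(method)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != n) stop("X and y disagree on the number of observations")
  p <- ncol(X)
  if (n - p < 2) stop("fewer than 2 residual degrees of freedom")
  qrX <- checkFixedRank(X)
  terms <- normalizeRandom(random, n)

  # noise-free degenerate case: all variance components at the zero boundary
  betaOLS <- qr.coef(qrX, y)
  rssOLS <- sum(qr.resid(qrX, y)^2)
  if (rssOLS <= 1e-20 * max(1, sum(y^2))) {
    vc <- setNames(rep(0, length(terms) + 1), c(names(terms), "residual"))
    blups <- lapply(terms, function(t) rep(0, ncol(t$U)))
    return(structure(list(vc = vc, loglik = NA_real_, aic = NA_real_,
      beta = betaOLS, betaCov = matrix(0, p, p), blups = blups,
      fitted = as.numeric(X %*% betaOLS), converged = TRUE,
      boundary = setNames(rep(TRUE, length(vc)), names(vc)),
      n = n, p = p, nVC = length(vc), method = "degenerate",
      xSignature = xSignature(X), y = y, X = X, randomTerms = terms),
      class = "remlFit"))
  }

  if (length(terms) == 0) return(remlOLS(y, X, qrX, terms))
  if (method == "spectral" && length(terms) != 1)
    stop("spectral path requires exactly one random term")
  if (method == "auto") method <- if (length(terms) == 1) "spectral" else "direct"
  fit <- if (method == "spectral") remlSpectral(y, X, terms, tol)
         else remlDirect(y, X, terms, tol, maxIter)
  fit$xSignature <- xSignature(X)
  fit$n <- n; fit$p <- p
  fit$nVC <- length(terms) + 1
  fit$aic <- -2 * fit$loglik + 2 * fit$nVC
  fit$y <- y; fit$X <- X; fit$randomTerms <- terms
  class(fit) <- "remlFit"
  fit
}

# OLS as a boundary case of the engine (no random terms): REML residual
# variance with n - p denominator
remlOLS <- function(y, X, qrX, terms) {
  n <- length(y); p <- ncol(X)
  beta <- qr.coef(qrX, y)
  r <- qr.resid(qrX, y)
  s2 <- sum(r^2) / (n - p)
  XtX <- crossprod(X)
  m2rl <- (n - p) * (log(2 * pi) + 1) + (n - p) * log(s2) +
    as.numeric(determinant(XtX)$modulus)
  structure(list(vc = c(residual = s2), loglik = -0.5 * m2rl,
    aic = m2rl + 2, beta = beta, betaCov = solve(XtX) * s2,
    blups = list(), fitted = as.numeric(X %*% beta), converged = TRUE,
    boundary = c(residual = FALSE), n = n, p = p, nVC = 1,
    method = "ols", xSignature = xSignature(X), y = y, X = X,
    randomTerms = terms), class = "remlFit")
}

remlSpectral <- function(y, X, terms, tol) {
  n <- length(y); p <- ncol(X)
  U <- terms[[1]]$U
  S <- tcrossprod(U)
  es <- eigen(S, symmetric = TRUE)
  d <- pmax(es$values, 0)
  Q <- es$vectors
  yt <- as.numeric(crossprod(Q, y))
  Xt <- crossprod(Q, X)

  eval1 <- function(logDelta) {
    w <- d + exp(logDelta)
    A <- crossprod(Xt / w, Xt)
    b <- crossprod(Xt / w, yt)
    beta <- solve(A, b)
    rt <- yt - as.numeric(Xt %*% beta)
    rss <- sum(rt^2 / w)
    s2u <- rss / (n - p)
    m2rl <- (n - p) * (log(2 * pi) + 1) + (n - p) * log(s2u) +
      sum(log(w)) + as.numeric(determinant(A)$modulus)
    list(m2rl = m2rl, s2u = s2u, beta = beta, A = A, rt = rt, w = w)
  }

  lo <- -25; hi <- 25
  opt <- optimize(function(ld) eval1(ld)$m2rl, c(lo, hi), tol = 1e-10)
  ld <- opt$minimum
  fin <- eval1(ld)
  delta <- exp(ld)
  s2u <- fin$s2u
  s2r <- delta * s2u
  boundary <- c(ld >= hi - 0.5, ld <= lo + 0.5)
  # BLUPs: u = s2u K Z' V^-1 (y - X beta)
  vr <- as.numeric(Q %*% (fin$rt / (s2u * fin$w)))
  u <- blupFromVinvResid(terms, c(s2u), vr)
  nm <- names(terms)
  structure(list(
    vc = setNames(c(s2u, s2r), c(nm, "residual")),
    loglik = -0.5 * fin$m2rl,
    beta = setNames(as.numeric(fin$beta), colnames(X)),
    betaCov = solve(fin$A) * s2u,
    blups = u, fitted = as.numeric(X %*% fin$beta) + randomContribution(terms, u),
    converged = TRUE,
    boundary = setNames(c(boundary[1], boundary[2]), c(nm, "residual")),
    method = "spectral", VinvResid = vr), class = "remlFit")
}

remlDirect <- function(y, X, terms, tol, maxIter) {
  n <- length(y); p <- ncol(X)
  A <- do.call(cbind, lapply(terms, function(t) t$U))
  q <- ncol(A)
  grp <- rep(seq_along(terms), vapply(terms, function(t) ncol(t$U), 0L))
  AtA <- crossprod(A); AtX <- crossprod(A, X); Aty <- as.numeric(crossprod(A, y))
  XtX <- crossprod(X); Xty <- as.numeric(crossprod(X, y)); yty <- sum(y^2)
  nt <- length(terms)

  core <- function(theta) {
    s2 <- exp(theta[seq_len(nt)]); s2r <- exp(theta[nt + 1])
    g <- s2[grp]
    M <- AtA + diag(s2r / g, q)
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    MiAtX <- backsolve(ch, forwardsolve(t(ch), AtX))
    MiAty <- backsolve(ch, forwardsolve(t(ch), Aty))
    XVX <- (XtX - crossprod(AtX, MiAtX)) / s2r
    XVy <- (Xty - as.numeric(crossprod(AtX, MiAty))) / s2r
    yVy <- (yty - sum(Aty * MiAty)) / s2r
    beta <- tryCatch(solve(XVX, XVy), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    yPy <- yVy - sum(XVy * beta)
    logdetV <- 2 * sum(log(diag(ch))) + sum(log(g)) + (n - q) * log(s2r)
    m2rl <- (n - p) * log(2 * pi) + logdetV +
      as.numeric(determinant(XVX)$modulus) + yPy
    list(m2rl = m2rl, s2 = s2, s2r = s2r, beta = beta, XVX = XVX, ch = ch)
  }
  negll <- function(theta) {
    cr <- core(theta)
    if (is.null(cr) || !is.finite(cr$m2rl)) return(1e10)
    cr$m2rl
  }

  v0 <- var(qr.resid(qr(X), y))
  theta0 <- log(rep(v0 / (nt + 1), nt + 1))
  opt <- optim(theta0, negll, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = max(maxIter * 10, 2000)))
  opt2 <- optim(opt$par, negll, method = "Nelder-Mead",
                control = list(reltol = 1e-12, maxit = max(maxIter * 5, 1000)))
  if (opt2$value < opt$value) opt <- opt2
  fin <- core(opt$par)
  s2 <- fin$s2; s2r <- fin$s2r
  boundary <- c(s2 < 1e-8 * v0, s2r < 1e-8 * v0)
  # V^-1 (y - X beta) via Woodbury
  r <- y - as.numeric(X %*% fin$beta)
  Atr <- as.numeric(crossprod(A, r))
  MiAtr <- backsolve(fin$ch, forwardsolve(t(fin$ch), Atr))
  vr <- (r - as.numeric(A %*% MiAtr)) / s2r
  u <- blupFromVinvResid(terms, s2, vr)
  structure(list(
    vc = setNames(c(s2, s2r), c(names(terms), "residual")),
    loglik = -0.5 * fin$m2rl,
    beta = setNames(as.numeric(fin$beta), colnames(X)),
    betaCov = solve(fin$XVX),
    blups = u, fitted = as.numeric(X %*% fin$beta) + randomContribution(terms, u),
    converged = opt$convergence == 0,
    boundary = setNames(boundary, c(names(terms), "residual")),
    method = "direct", VinvResid = vr), class = "remlFit")
}

blupFromVinvResid <- function(terms, s2, vr) {
  u <- vector("list", length(terms))
  names(u) <- names(terms)
  for (k in seq_along(terms)) {
    Z <- terms[[k]]$Z; K <- terms[[k]]$K
    zv <- if (is.null(Z)) vr else as.numeric(crossprod(Z, vr))
    u[[k]] <- s2[k] * (if (is.null(K)) zv else as.numeric(K %*% zv))
    if (!is.null(K) && !is.null(rownames(K))) names(u[[k]]) <- rownames(K)
    else if (!is.null(Z) && !is.null(colnames(Z))) names(u[[k]]) <- colnames(Z)
  }
  u
}

randomContribution <- function(terms, u) {
  out <- 0
  for (k in seq_along(terms)) {
    Z <- terms[[k]]$Z
    out <- out + if (is.null(Z)) u[[k]] else as.numeric(Z %*% u[[k]])
  }
  out
}

#' @export
print.remlFit <- function(x, ...) {
  cat("REML fit (", x$method, " path), logRL = ", format(x$loglik), "\n", sep = "")
  cat("variance components:\n"); print(x$vc)
  if (any(x$boundary)) cat("boundary estimates:",
                           paste(names(x$vc)[x$boundary], collapse = ", "), "\n")
  invisible(x)
}

#' Solve the mixed-model equations at fixed variance components
#'
#' Henderson's equations in the \code{u = K a} parametrisation, which avoids
#' inverting the (possibly singular) covariance kernels: for each random term
#' \eqn{Z_k' X \beta + \sum_l Z_k' Z_l K_l a_l + \lambda_k a_k = Z_k' y} with
#' \eqn{\lambda_k = \sigma^2_r / \sigma^2_k}, jointly with the fixed-effect
#' normal equations. Exact for positive semidefinite kernels.
#'
#' @param y,X,random as in \code{\link{fitREML}}.
#' @param vc named variance components (one per random term plus
#'   \code{residual}), all strictly positive.
#' @return list with \code{beta}, \code{u} (named list of BLUPs), and
#'   \code{fitted}.
#' @export
solveMME <- function(y, X = NULL, random = list(), vc) {
  y <- as.numeric(y); n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  terms <- normalizeRandom(random, n)
  if (!all(c(names(terms), "residual") %in% names(vc)))
    stop("vc must name every random term and 'residual'")
  s2r <- vc[["residual"]]
  s2 <- vapply(names(terms), function(nm) vc[[nm]], 0)
  if (any(c(s2, s2r) <= 0)) stop("variance components must be strictly positive")
  Zs <- lapply(terms, function(t) if (is.null(t$Z)) diag(n) else t$Z)
  Ks <- lapply(seq_along(terms), function(k) {
    K <- terms[[k]]$K
    if (is.null(K)) diag(ncol(Zs[[k]])) else K
  })
  qk <- vapply(Zs, ncol, 0L)
  p <- ncol(X)
  dim <- p + sum(qk)
  C <- matrix(0, dim, dim)
  rhs <- numeric(dim)
  C[1:p, 1:p] <- crossprod(X)
  rhs[1:p] <- crossprod(X, y)
  off <- p + c(0, cumsum(qk))[seq_along(qk)]
  for (k in seq_along(terms)) {
    ik <- off[k] + seq_len(qk[k])
    ZkX <- crossprod(Zs[[k]], X)
    C[ik, 1:p] <- ZkX
    C[1:p, ik] <- crossprod(X, Zs[[k]] %*% Ks[[k]])
    rhs[ik] <- crossprod(Zs[[k]], y)
    for (l in seq_along(terms)) {
      il <- off[l] + seq_len(qk[l])
      C[ik, il] <- crossprod(Zs[[k]], Zs[[l]] %*% Ks[[l]])
    }
    C[ik, ik] <- C[ik, ik] + diag(s2r / s2[k], qk[k])
  }
  sol <- tryCatch(solve(C, rhs),
                  error = function(e) stop("singular mixed-model coefficient matrix"))
  beta <- setNames(sol[1:p], colnames(X))
  u <- lapply(seq_along(terms), function(k) {
    a <- sol[off[k] + seq_len(qk[k])]
    uk <- as.numeric(Ks[[k]] %*% a)
    K <- terms[[k]]$K
    if (!is.null(K) && !is.null(rownames(K))) names(uk) <- rownames(K)
    uk
  })
  names(u) <- names(terms)
  fitted <- as.numeric(X %*% beta) + randomContribution(terms, u)
  list(beta = beta, u = u, fitted = fitted)
}

#' Compare fits by Akaike's information criterion
#'
#' AIC here is \eqn{-2 \log RL + 2 q} with \eqn{q} the number of estimated
#' variance parameters. Restricted likelihoods are only comparable across
#' models sharing the same fixed design, so mismatching fixed parts raise an
#' error.
#'
#' @param ... \code{remlFit} objects.
#' @return data.frame with one row per fit, ordered as given.
#' @export
compareAIC <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "remlFit"))
    fits <- fits[[1]]
  sigs <- vapply(fits, function(f) f$xSignature, "")
  if (length(unique(sigs)) > 1)
    stop("AIC comparison requires identical fixed designs")
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  data.frame(model = nm,
             aic = vapply(fits, function(f) f$aic, 0),
             loglik = vapply(fits, function(f) f$loglik, 0),
             nVC = vapply(fits, function(f) f$nVC, 0))
}
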