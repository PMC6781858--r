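# Desired-gains genomic selection index combining winter-hardiness and
# frost-tolerance predictions: Index_i = X_WINT,i b_WINT + X_FROST,i b_FROST
# with weights b = G^-1 a, G the 2x2 covariance of the predicted values and a
# the desired-gains vector (default one genetic standard deviation per trait,
# i.e. a = diag(G)).

asGebvVector <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  if (is.data.frame(x) && all(c("line", "value") %in% names(x)))
    return(setNames(x$value, as.character(x$line)))
  stop("cannot interpret GEBV input")
}

#' Desired-gains index weights
#'
#' Estimates the 2x2 variance-covariance matrix G of the two traits'
#' predicted values across the shared candidate lines and solves G b = a.
#' Both traits are assumed lower-is-better; a trait declared
#' \code{"higher"}-is-better is sign-flipped internally so the index stays on
#' a lower-is-better scale. Leaving mixed directions undeclared is an error.
#'
#' @param gebvWint,gebvFrost predicted values (\code{gebvTable} or named
#'   vectors) for the two traits.
#' @param desiredGains \code{"default"} (one SD gain per trait, a = diag(G))
#'   or a numeric length-2 vector.
#' @param traitDirections character length-2 over \{"lower","higher"\}.
#' @param standardize center and scale each trait's predictions across the
#'   candidate lines before estimating G (default TRUE). The two traits live
#'   on incommensurate scales (a 1-9 score versus a damage percentage); on
#'   raw scales the desired-gains solve is dominated by the larger-variance
#'   trait and can assign the other a negative weight, so the weights are
#'   made scale-free by default. \code{FALSE} gives the raw-scale solve.
#' @return list of class \code{indexWeights}: \code{b} (named weights),
#'   \code{G}, \code{a}, \code{lines} used, and the centering/scaling
#'   applied.
#' @export
computeIndexWeights <- function(gebvWint, gebvFrost, desiredGains = "default",
                                traitDirections = c("lower", "lower"),
                                standardize = TRUE) {
  w <- asGebvVector(gebvWint)
  f <- asGebvVector(gebvFrost)
  if (!all(traitDirections %in% c("lower", "higher")))
    stop("traitDirections must be 'lower' or 'higher'")
  if (traitDirections[1] == "higher") w <- -w
  if (traitDirections[2] == "higher") f <- -f
  shared <- intersect(names(w), names(f))
  if (length(shared) < 3) stop("fewer than 3 shared lines")
  X <- cbind(wint = w[shared], frost = f[shared])
  if (any(apply(X, 2, sd) < 1e-24))
    stop("zero-variance predictions; index weights undefined")
  center <- c(0, 0); scale_ <- c(1, 1)
  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, sd)
    X <- scale(X, center = center, scale = scale_)
  }
  G <- cov(X)
  if (any(diag(G) < 1e-24))
    stop("zero-variance predictions; index weights undefined")
  r <- G[1, 2] / sqrt(G[1, 1] * G[2, 2])
  if (abs(r) > 1 - 1e-10)
    stop("singular G: predictions nearly perfectly correlated; ",
         "restrict to a single trait instead")
  a <- if (identical(desiredGains, "default")) diag(G) else {
    if (length(desiredGains) != 2) stop("desiredGains must have length 2")
    as.numeric(desiredGains)
  }
  b <- solve(G, a)
  structure(list(b = setNames(as.numeric(b), c("wint", "frost")), G = G,
                 a = setNames(as.numeric(a), c("wint", "frost")),
                 lines = shared,
                 center = setNames(center, c("wint", "frost")),
                 scale = setNames(scale_, c("wint", "frost")),
                 directions = traitDirections), class = "indexWeights")
}

#' Index values for candidate lines
#'
#' Applies index weights to the shared lines of the two prediction tables;
#' lines present in only one table are excluded with a warning.
#'
#' @param weights an \code{indexWeights} object.
#' @param gebvWint,gebvFrost predicted values for the two traits.
#' @return \code{gebvTable} with model tag \code{"index"}.
#' @export
computeIndexValues <- function(weights, gebvWint, gebvFrost) {
  w <- asGebvVector(gebvWint)
  f <- asGebvVector(gebvFrost)
  if (weights$directions[1] == "higher") w <- -w
  if (weights$directions[2] == "higher") f <- -f
  shared <- intersect(names(w), names(f))
  only <- c(setdiff(names(w), shared), setdiff(names(f), shared))
  if (length(only))
    warning("lines present for a single trait excluded: ",
            paste(only, collapse = ", "))
  if (length(shared) == 0) stop("no shared lines")
  wS <- (w[shared] - weights$center["wint"]) / weights$scale["wint"]
  fS <- (f[shared] - weights$center["frost"]) / weights$scale["frost"]
  vals <- weights$b["wint"] * wS + weights$b["frost"] * fS
  gebvTable(shared, vals, "index")
}

#' @export
print.indexWeights <- function(x, ...) {
  cat("Desired-gains index weights over", length(x$lines), "lines\n")
  cat(sprintf("  b_wint = %.4g, b_frost = %.4g\n", x$b["wint"], x$b["frost"]))
  invisible(x)
}
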