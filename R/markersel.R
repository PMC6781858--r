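# Two-stage marker pre-selection for marker-assisted prediction: association
# results feed either a chromosome-wise stepwise stage (top markers per
# chromosome, 1-6 kept each) pooled and reduced again, or a single
# genome-wide stepwise reduction. Forward selection minimises the AIC of the
# OLS fit on the training BLUEs; ties in p-values break by larger absolute
# effect, then map order.

olsAIC <- function(y, Xm) {
  X <- if (is.null(Xm)) matrix(1, length(y), 1) else cbind(1, Xm)
  ft <- lm.fit(X, y)
  rss <- sum(ft$residuals^2)
  n <- length(y)
  n * log(max(rss, 1e-300) / n) + 2 * (ft$rank + 1)
}

# forward stepwise over candidate marker columns; the first marker is always
# taken (best single-marker AIC), later additions need strict improvement
forwardStepwise <- function(y, M, candidates, cap) {
  selected <- character(0)
  curAIC <- olsAIC(y, NULL)
  audit <- data.frame(step = integer(0), marker = character(0), aic = numeric(0))
  pool <- candidates
  step <- 0
  while (length(selected) < cap && length(pool) > 0) {
    step <- step + 1
    aics <- vapply(pool, function(m)
      olsAIC(y, M[, c(selected, m), drop = FALSE]), 0)
    best <- which.min(aics)
    if (step > 1 && aics[best] >= curAIC - 1e-9) break
    selected <- c(selected, pool[best])
    curAIC <- aics[best]
    audit <- rbind(audit, data.frame(step = step, marker = pool[best],
                                     aic = curAIC))
    pool <- pool[-best]
  }
  list(selected = selected, audit = audit)
}

orderGwas <- function(gwas) gwas[order(gwas$p, -abs(gwas$beta)), , drop = FALSE]

markerSubset <- function(markers, route, audit) {
  structure(list(markers = markers, route = route, audit = audit),
            class = "markerSubset")
}

#' @export
print.markerSubset <- function(x, ...) {
  cat("Marker subset (", x$route, "): ", length(x$markers), " markers\n",
      sep = "")
  cat(" ", paste(x$markers, collapse = ", "), "\n")
  invisible(x)
}

#' Chromosome-wise two-stage marker pre-selection
#'
#' Stage 1: per chromosome, the \code{perChromTop} markers with the smallest
#' association p-values enter a forward stepwise regression keeping 1 to
#' \code{perChromMax} of them. Stage 2: the pooled survivors (a genome-wide
#' distributed set) are reduced by a second stepwise regression to at most
#' \code{finalCap} markers.
#'
#' @param gwas association scan result (\code{\link{gwasScan}}).
#' @param trainBlues named numeric vector / BLUE table of training lines.
#' @param geno complete \linkS4class{GenotypeData}.
#' @param perChromTop markers entering the per-chromosome stage (default 12).
#' @param perChromMax markers kept per chromosome (default 6).
#' @param finalCap final subset cap (default 21; must leave at least 2
#'   residual degrees of freedom in the training OLS).
#' @return \code{markerSubset}: markers, route, and a per-stage audit trail.
#' @export
selectChromosomeWise <- function(gwas, trainBlues, geno, perChromTop = 12,
                                 perChromMax = 6, finalCap = 21) {
  y <- asBlueVector(trainBlues)
  if (finalCap > length(y) - 2)
    stop("finalCap exceeds training size minus 2; stepwise not identifiable")
  M <- genoCodes(geno)[names(y), , drop = FALSE]
  gwas <- gwas[gwas$flag == "", , drop = FALSE]
  stage1 <- list()
  pooled <- character(0)
  for (cc in sort(unique(gwas$chrom))) {
    sub <- orderGwas(gwas[gwas$chrom == cc, , drop = FALSE])
    cand <- head(sub$marker, perChromTop)
    st <- forwardStepwise(y, M, cand, perChromMax)
    stage1[[as.character(cc)]] <- list(candidates = cand, selected = st$selected,
                                       audit = st$audit)
    pooled <- c(pooled, st$selected)
  }
  st2 <- forwardStepwise(y, M, pooled, finalCap)
  markerSubset(st2$selected, "chromosome-wise",
               list(stage1 = stage1,
                    stage2 = list(candidates = pooled, audit = st2$audit)))
}

#' Genome-wide stepwise marker pre-selection
#'
#' Single-stage variant: forward stepwise regression over the \code{top}
#' genome-wide most significant markers, reduced to at most \code{finalCap}.
#'
#' @inheritParams selectChromosomeWise
#' @param top size of the initial most-significant set (default 126).
#' @return \code{markerSubset}.
#' @export
selectGenomeWide <- function(gwas, trainBlues, geno, top = 126, finalCap = 21) {
  y <- asBlueVector(trainBlues)
  if (finalCap > length(y) - 2)
    stop("finalCap exceeds training size minus 2; stepwise not identifiable")
  M <- genoCodes(geno)[names(y), , drop = FALSE]
  gwas <- orderGwas(gwas[gwas$flag == "", , drop = FALSE])
  cand <- head(gwas$marker, top)
  st <- forwardStepwise(y, M, cand, finalCap)
  markerSubset(st$selected, "genome-wide",
               list(candidates = cand, audit = st$audit))
}

#' Random marker baseline
#'
#' Uniform sample of markers without replacement, the baseline against which
#' pre-selected subsets are compared.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param n subset size (<= number of markers).
#' @param seed integer seed.
#' @return \code{markerSubset} with route \code{"random"}.
#' @export
sampleRandomMarkers <- function(geno, n, seed) {
  if (n > nMarkers(geno)) stop("n exceeds the number of markers")
  mk <- withSeed(seed, sample(markerIds(geno), n))
  markerSubset(mk, "random", list(seed = seed))
}
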