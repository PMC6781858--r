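# Stage-1 (within-trial) and stage-2 (across-trial) phenotypic analysis.
# Every trial is analysed twice, following the standard two-pass scheme:
# genotype random to estimate the genetic variance, then genotype fixed to
# obtain BLUEs and the mean variance of a difference (MVD) feeding the
# entry-mean heritability h2 = sigma2G / (sigma2G + MVD/2).

asBlueVector <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  if (is.data.frame(x)) {
    vcol <- intersect(c("blue", "value"), names(x))[1]
    if (is.na(vcol) || !"line" %in% names(x))
      stop("BLUE table needs columns 'line' and 'blue' (or 'value')")
    return(setNames(x[[vcol]], as.character(x$line)))
  }
  stop("cannot interpret BLUE input")
}

# mean over all line pairs of var(BLUE_i - BLUE_j) from the BLUE covariance
meanVarDiff <- function(Cb) {
  N <- nrow(Cb)
  2 * (N * sum(diag(Cb)) - sum(Cb)) / (N * (N - 1))
}

designZ <- function(f) {
  f <- factor(f)
  Z <- model.matrix(~ 0 + f)
  colnames(Z) <- levels(f)
  Z
}

# shared two-pass machinery: random-genotype fit for sigma2G, fixed-genotype
# fit for BLUEs / MVD. extraRandom is a named list of design factors.
twoPassAnalysis <- function(line, value, extraRandom = list(),
                            extraFixed = NULL) {
  line <- factor(line)
  randR <- c(list(line = list(Z = designZ(line), K = NULL)),
             lapply(extraRandom, function(f) list(Z = designZ(f), K = NULL)))
  Xbase <- if (is.null(extraFixed)) matrix(1, length(value), 1,
                                           dimnames = list(NULL, "(Intercept)"))
           else extraFixed
  fitR <- fitREML(value, Xbase, randR)
  sigma2G <- unname(fitR$vc["line"])
  Xg <- model.matrix(~ line)
  if (!is.null(extraFixed))
    Xg <- cbind(Xg, extraFixed[, -1, drop = FALSE])
  randF <- lapply(extraRandom, function(f) list(Z = designZ(f), K = NULL))
  fitF <- fitREML(value, Xg, randF)
  # BLUE_i = mu + g_i (+ mean of any extra fixed effects, constant across lines)
  lev <- levels(line)
  L <- matrix(0, length(lev), ncol(Xg), dimnames = list(lev, colnames(Xg)))
  L[, "(Intercept)"] <- 1
  for (i in seq_along(lev)[-1]) L[i, paste0("line", lev[i])] <- 1
  extraCols <- setdiff(colnames(Xg), c("(Intercept)", paste0("line", lev)))
  if (length(extraCols))
    L[, extraCols] <- matrix(colMeans(Xg[, extraCols, drop = FALSE]),
                             length(lev), length(extraCols), byrow = TRUE)
  blue <- as.numeric(L %*% fitF$beta)
  Cb <- L %*% fitF$betaCov %*% t(L)
  MVD <- meanVarDiff(Cb)
  h2 <- sigma2G / (sigma2G + MVD / 2)
  list(blues = data.frame(line = lev, blue = blue, se = sqrt(pmax(diag(Cb), 0)),
                          row.names = NULL),
       h2 = h2, sigma2G = sigma2G, MVD = MVD,
       randomFit = fitR, fixedFit = fitF)
}

dropEmptyLines <- function(pheno) {
  ok <- !is.na(pheno$value)
  gone <- setdiff(unique(pheno$line), unique(pheno$line[ok]))
  if (length(gone))
    warning("lines without any observation excluded: ",
            paste(gone, collapse = ", "))
  pheno[ok & !(pheno$line %in% gone), , drop = FALSE]
}

#' Analyse a complete-block frost experiment
#'
#' Mixed model y = mu + line + block + residual with random blocks. The line
#' effect is first fitted random to estimate the genetic variance, then fixed
#' to obtain BLUEs; the entry-mean heritability uses the mean variance of a
#' difference of the BLUEs.
#'
#' @param pheno long-format phenotype table with columns \code{line},
#'   \code{block}, \code{value} (rows with missing values are dropped; lines
#'   losing all observations are excluded with a warning).
#' @return list of class \code{phenoAnalysis}: \code{blues} (line, blue, se),
#'   \code{h2}, \code{sigma2G}, \code{MVD}, and the two underlying
#'   \code{remlFit}s.
#' @export
fitFrostModel <- function(pheno) {
  pheno <- dropEmptyLines(pheno)
  if (length(unique(pheno$block)) < 2) stop("need at least 2 blocks")
  out <- twoPassAnalysis(pheno$line, pheno$value,
                         extraRandom = list(block = pheno$block))
  structure(c(out, list(trial = unique(as.character(pheno$trial)))),
            class = "phenoAnalysis")
}

#' Analyse a field trial with spatial model selection
#'
#' Fits the candidate model set (random block, optionally plus random row
#' and/or column effects within blocks, iid residuals) with genotype random,
#' selects the best model by AIC, and re-fits the winner with genotype fixed
#' for BLUEs and heritability. Trials with h2 at or below
#' \code{h2Threshold} are flagged as excluded from further analysis.
#'
#' @param pheno long table with columns \code{line}, \code{block},
#'   \code{row}, \code{column}, \code{value}.
#' @param candidates list of character vectors over \{"block","row","column"\}.
#' @param h2Threshold exclusion threshold on the entry-mean heritability
#'   (default 0.3).
#' @return \code{phenoAnalysis} list, plus \code{chosenModel},
#'   \code{aicTable}, and logical \code{excluded}.
#' @export
fitTrialModel <- function(pheno,
                          candidates = list("block", c("block", "row"),
                                            c("block", "column"),
                                            c("block", "row", "column")),
                          h2Threshold = 0.3) {
  if (length(candidates) == 0) stop("empty candidate model list")
  pheno <- dropEmptyLines(pheno)
  need <- unique(unlist(candidates))
  if (!all(need %in% names(pheno)))
    stop("phenotype table lacks design columns: ",
         paste(setdiff(need, names(pheno)), collapse = ", "))
  mkFactor <- function(t) {
    if (t == "block") factor(pheno$block)
    else interaction(pheno$block, pheno[[t]], drop = TRUE)
  }
  factors <- setNames(lapply(need, mkFactor), need)
  line <- factor(pheno$line)
  fits <- lapply(candidates, function(terms) {
    rand <- c(list(line = list(Z = designZ(line), K = NULL)),
              setNames(lapply(terms, function(t) list(Z = designZ(factors[[t]]),
                                                      K = NULL)), terms))
    fitREML(pheno$value, NULL, rand)
  })
  names(fits) <- vapply(candidates, paste, "", collapse = "+")
  tab <- compareAIC(fits)
  best <- which.min(tab$aic)
  winner <- candidates[[best]]
  out <- twoPassAnalysis(pheno$line, pheno$value,
                         extraRandom = setNames(
                           lapply(winner, function(t) factors[[t]]), winner))
  out$chosenModel <- names(fits)[best]
  out$aicTable <- tab
  out$excluded <- out$h2 <= h2Threshold
  out$trial <- unique(as.character(pheno$trial))
  structure(out, class = "phenoAnalysis")
}

#' Across-trial analysis of stage-1 BLUEs
#'
#' Second-stage model y_ij = mu + g_i + t_j + e_ij with fixed trial effects
#' and a pooled random effect absorbing trial-by-line interaction and
#' residual. Genotype is fitted random for the genetic variance, then fixed
#' for across-trial BLUEs and heritability.
#'
#' @param bluesByTrial list of stage-1 BLUE tables (data.frames with columns
#'   \code{line}, \code{blue}; names or a \code{trial} column identify
#'   trials).
#' @return \code{phenoAnalysis} list; with a single trial, the input is
#'   passed through with a warning and \code{h2 = NA}.
#' @export
acrossTrialModel <- function(bluesByTrial) {
  if (length(bluesByTrial) < 1) stop("no trials supplied")
  if (length(bluesByTrial) == 1) {
    warning("single trial: across-trial analysis is an identity pass-through")
    b <- bluesByTrial[[1]]
    return(structure(list(blues = b[, c("line", "blue", "se")[c("line", "blue", "se") %in% names(b)]],
                          h2 = NA_real_, sigma2G = NA_real_, MVD = NA_real_),
                     class = "phenoAnalysis"))
  }
  if (is.null(names(bluesByTrial)))
    names(bluesByTrial) <- paste0("T", seq_along(bluesByTrial))
  long <- do.call(rbind, lapply(names(bluesByTrial), function(tr) {
    b <- bluesByTrial[[tr]]
    data.frame(line = as.character(b$line), trial = tr, value = b$blue)
  }))
  shared <- Reduce(intersect, lapply(bluesByTrial, function(b) as.character(b$line)))
  if (length(shared) < 2) stop("trials share fewer than 2 lines")
  # connectivity of the line-by-trial incidence
  lines <- unique(long$line)
  comp <- setNames(rep(NA_integer_, length(lines)), lines)
  cid <- 0
  for (ln in lines) {
    if (!is.na(comp[ln])) next
    cid <- cid + 1
    frontier <- ln
    while (length(frontier)) {
      comp[frontier] <- cid
      tr <- unique(long$trial[long$line %in% frontier])
      nxt <- unique(long$line[long$trial %in% tr])
      frontier <- nxt[is.na(comp[nxt])]
    }
  }
  if (max(comp) > 1) stop("disconnected line/trial structure")
  trialX <- model.matrix(~ factor(long$trial))
  colnames(trialX) <- c("(Intercept)",
                        paste0("trial", levels(factor(long$trial))[-1]))
  out <- twoPassAnalysis(long$line, long$value, extraRandom = list(),
                         extraFixed = trialX)
  structure(out, class = "phenoAnalysis")
}

#' Correlations of one trait's BLUEs with a set of other traits
#'
#' Pearson correlations on shared lines with two-sided significance at
#' alpha = 0.05.
#'
#' @param bluesA reference BLUE table (or named vector).
#' @param bluesB a BLUE table / named vector or a named list of them.
#' @param alpha significance level (default 0.05).
#' @return data.frame with trait, n (shared lines), r, p, significant.
#' @export
traitCorrelations <- function(bluesA, bluesB, alpha = 0.05) {
  a <- asBlueVector(bluesA)
  if (!is.list(bluesB) || is.data.frame(bluesB)) bluesB <- list(trait = bluesB)
  rows <- lapply(names(bluesB), function(nm) {
    b <- asBlueVector(bluesB[[nm]])
    shared <- intersect(names(a), names(b))
    if (length(shared) < 3) stop("fewer than 3 shared lines for trait ", nm)
    ct <- cor.test(a[shared], b[shared], method = "pearson")
    data.frame(trait = nm, n = length(shared), r = unname(ct$estimate),
               p = ct$p.value, significant = ct$p.value < alpha)
  })
  do.call(rbind, rows)
}

#' @export
print.phenoAnalysis <- function(x, ...) {
  cat("Phenotypic analysis:", nrow(x$blues), "line BLUEs\n")
  if (!is.null(x$chosenModel)) cat("  chosen spatial model:", x$chosenModel, "\n")
  cat(sprintf("  sigma2G = %.4g, MVD = %.4g, h2 = %.3f\n",
              x$sigma2G, x$MVD, x$h2))
  if (isTRUE(x$excluded)) cat("  flagged: h2 below threshold\n")
  invisible(x)
}
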