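# Resampling evaluation: heritability-scaled prediction accuracy, replicated
# cross-validation within a population, and independent validation across
# populations including the two-trait selection index. Marker pre-selection
# (association scan + stepwise) is re-run inside every training split so that
# no information leaks from validation lines into the models.

#' Heritability-scaled prediction accuracy
#'
#' Pearson correlation between predicted and observed values on shared lines,
#' divided by the square root of the heritability of the observed data. Not
#' clipped at 1.
#'
#' @param predicted \code{gebvTable} or named numeric vector.
#' @param observed BLUE table or named numeric vector.
#' @param h2 heritability of the observed experiment (scalar in (0,1] or a
#'   \code{phenoAnalysis} object).
#' @return numeric accuracy.
#' @export
predictionAccuracy <- function(predicted, observed, h2) {
  p <- asGebvVector(predicted)
  o <- asBlueVector(observed)
  if (inherits(h2, "phenoAnalysis")) h2 <- h2$h2
  if (!is.finite(h2) || h2 <= 0) stop("h2 must be > 0")
  shared <- intersect(names(p), names(o))
  if (length(shared) < 3) stop("fewer than 3 shared lines")
  if (sd(p[shared]) < 1e-12) stop("zero-variance predictions; accuracy undefined")
  cor(p[shared], o[shared]) / sqrt(h2)
}

#' Resampling scheme for model evaluation
#'
#' @param nReplicates resampling replicates (default 100).
#' @param nTrain training-set size per replicate (default 130).
#' @param nValidation validation-set size per replicate (default 30).
#' @param seed integer base seed; replicate r uses a seed derived from it.
#' @param mode \code{"within"} (train and validation sampled disjointly from
#'   one population) or \code{"independent"} (training pools and validation
#'   pool are different populations).
#' @return list of class \code{cvScheme}.
#' @export
cvScheme <- function(nReplicates = 100, nTrain = 130, nValidation = 30,
                     seed = 1, mode = c("within", "independent")) {
  mode <- match.arg(mode)
  if (nValidation < 1) stop("nValidation must be >= 1")
  if (nTrain < 3) stop("nTrain must be >= 3")
  structure(list(nReplicates = nReplicates, nTrain = nTrain,
                 nValidation = nValidation, seed = seed, mode = mode),
            class = "cvScheme")
}

#' Prediction model specification
#'
#' @param type \code{"GS"} (GBLUP, all markers), \code{"wGS"} (GBLUP plus a
#'   fixed haploblock effect), or \code{"MAS"} (RR-BLUP on a reduced marker
#'   set).
#' @param route for MAS: \code{"chromwise"}, \code{"genomewide"} or
#'   \code{"random"} marker pre-selection.
#' @param nMarkers MAS subset cap (default 21).
#' @param haploblock \linkS4class{Haploblock} for wGS models.
#' @param name display name (defaulted from the settings).
#' @return list of class \code{modelSpec}.
#' @export
modelSpec <- function(type = c("GS", "wGS", "MAS"),
                      route = c("chromwise", "genomewide", "random"),
                      nMarkers = 21, haploblock = NULL, name = NULL) {
  type <- match.arg(type)
  route <- match.arg(route)
  if (type == "wGS" && is.null(haploblock))
    stop("wGS model needs a haploblock")
  if (is.null(name))
    name <- switch(type, GS = "GS",
                   wGS = paste0("wGS_", haploblock@name),
                   MAS = paste0("MAS_", route, "_", nMarkers))
  structure(list(type = type, route = route, nMarkers = nMarkers,
                 haploblock = haploblock, name = name), class = "modelSpec")
}

# fit one model spec on a training split and predict the validation lines
fitModelSpec <- function(spec, blues, geno, K, train, val, repSeed) {
  yTrain <- blues[train]
  if (spec$type == "GS") {
    gblupPredict(yTrain, K, val)
  } else if (spec$type == "wGS") {
    wblupPredict(yTrain, K, spec$haploblock, val)
  } else {
    subset <- switch(spec$route,
      random = sampleRandomMarkers(geno, spec$nMarkers, repSeed),
      chromwise = selectChromosomeWise(gwasScan(yTrain, geno, K), yTrain, geno,
                                       finalCap = spec$nMarkers),
      genomewide = selectGenomeWide(gwasScan(yTrain, geno, K), yTrain, geno,
                                    finalCap = spec$nMarkers))
    out <- rrblupPredict(yTrain, geno, subset$markers, val)$gebv
    attr(out, "markers") <- subset$markers
    out
  }
}

accuracyReport <- function(acc, scheme, extra = list()) {
  summ <- do.call(rbind, lapply(split(acc$accuracy, acc$model), function(v) {
    data.frame(mean = mean(v), sd = sd(v), cv = sd(v) / abs(mean(v)))
  }))
  summ <- data.frame(model = rownames(summ), summ, row.names = NULL)
  structure(c(list(accuracies = acc, summary = summ, scheme = scheme), extra),
            class = "accuracyReport")
}

#' @export
print.accuracyReport <- function(x, ...) {
  cat("Prediction accuracy over", x$scheme$nReplicates, "replicates",
      sprintf("(train %d / validation %d)\n", x$scheme$nTrain,
              x$scheme$nValidation))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Replicated cross-validation within a population
#'
#' Per replicate, disjoint training and validation sets of the configured
#' sizes are sampled, every model is trained on the training split only
#' (including the association scan and stepwise marker selection for MAS
#' models, re-run inside each replicate), and accuracy is the
#' heritability-scaled correlation on the validation lines.
#'
#' @param blues named numeric vector (or BLUE table) for the whole dataset.
#' @param geno complete \linkS4class{GenotypeData} covering those lines.
#' @param K kinship matrix covering those lines.
#' @param h2 heritability of the phenotypic data.
#' @param scheme a \code{\link{cvScheme}}.
#' @param models list of \code{\link{modelSpec}}s.
#' @return \code{accuracyReport}: per-replicate accuracies and a summary
#'   (mean, sd, coefficient of variation) per model.
#' @export
crossValidate <- function(blues, geno, K, h2, scheme, models) {
  blues <- asBlueVector(blues)
  lines <- names(blues)
  if (length(lines) < scheme$nTrain + scheme$nValidation)
    stop("dataset smaller than nTrain + nValidation")
  if (inherits(models, "modelSpec")) models <- list(models)
  rows <- vector("list", scheme$nReplicates * length(models))
  splits <- vector("list", scheme$nReplicates)
  k <- 0
  for (r in seq_len(scheme$nReplicates)) {
    repSeed <- scheme$seed + 1009L * r
    split_ <- withSeed(repSeed, {
      train <- sample(lines, scheme$nTrain)
      val <- sample(setdiff(lines, train), scheme$nValidation)
      list(train = train, val = val)
    })
    splits[[r]] <- split_
    for (spec in models) {
      pred <- fitModelSpec(spec, blues, geno, K, split_$train, split_$val,
                           repSeed)
      k <- k + 1
      rows[[k]] <- data.frame(model = spec$name, replicate = r,
                              accuracy = predictionAccuracy(pred,
                                blues[split_$val], h2))
    }
  }
  accuracyReport(do.call(rbind, rows), scheme, extra = list(splits = splits))
}

#' Independent validation with a two-trait selection index
#'
#' Prediction models are trained on resampled training sets from two
#' trait-specific pools (winter hardiness and frost tolerance) and evaluated
#' against a third, independently phenotyped validation pool. For every model
#' specification the two single-trait predictions are also combined by the
#' desired-gains index (\code{\link{computeIndexWeights}}, G estimated from
#' the validation-line predictions).
#'
#' @param trainWinter,trainFrost lists with elements \code{blues} (named
#'   vector over that pool's lines) and \code{h2}.
#' @param validBlues named vector of the validation pool's observed BLUEs.
#' @param validH2 heritability of the validation experiment (used to scale
#'   all accuracies).
#' @param geno,K marker data and kinship covering all pools.
#' @param scheme a \code{\link{cvScheme}}; \code{nValidation} lines are drawn
#'   from the validation pool each replicate (the whole pool if equal).
#' @param models list of \code{\link{modelSpec}}s.
#' @return \code{accuracyReport} with models \code{<name>_winter},
#'   \code{<name>_frost} and \code{<name>_index}; for MAS models the size of
#'   the union of the two trait-specific marker subsets is recorded in
#'   \code{markerUnion}.
#' @export
independentValidate <- function(trainWinter, trainFrost, validBlues, validH2,
                                geno, K, scheme, models) {
  validBlues <- asBlueVector(validBlues)
  poolW <- names(asBlueVector(trainWinter$blues))
  poolF <- names(asBlueVector(trainFrost$blues))
  poolV <- names(validBlues)
  if (length(poolV) < scheme$nValidation)
    stop("validation pool smaller than nValidation")
  if (inherits(models, "modelSpec")) models <- list(models)
  rows <- list(); unions <- list()
  splits <- vector("list", scheme$nReplicates)
  for (r in seq_len(scheme$nReplicates)) {
    repSeed <- scheme$seed + 1009L * r
    s <- withSeed(repSeed, list(
      trW = sample(poolW, min(scheme$nTrain, length(poolW))),
      trF = sample(poolF, min(scheme$nTrain, length(poolF))),
      val = sample(poolV, scheme$nValidation)))
    splits[[r]] <- s
    for (spec in models) {
      predW <- fitModelSpec(spec, asBlueVector(trainWinter$blues), geno, K,
                            s$trW, s$val, repSeed)
      predF <- fitModelSpec(spec, asBlueVector(trainFrost$blues), geno, K,
                            s$trF, s$val, repSeed + 1L)
      wts <- computeIndexWeights(predW, predF)
      predI <- computeIndexValues(wts, predW, predF)
      for (nm in c("winter", "frost", "index")) {
        pred <- switch(nm, winter = predW, frost = predF, index = predI)
        rows[[length(rows) + 1]] <- data.frame(
          model = paste0(spec$name, "_", nm), replicate = r,
          accuracy = predictionAccuracy(pred, validBlues[s$val], validH2))
      }
      if (spec$type == "MAS")
        unions[[length(unions) + 1]] <- data.frame(
          model = spec$name, replicate = r,
          nWinter = length(attr(predW, "markers")),
          nFrost = length(attr(predF, "markers")),
          nUnion = length(union(attr(predW, "markers"),
                                attr(predF, "markers"))))
    }
  }
  accuracyReport(do.call(rbind, rows), scheme,
                 extra = list(markerUnion = if (length(unions))
                   do.call(rbind, unions) else NULL, splits = splits))
}
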