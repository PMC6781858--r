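# Genomic and marker-assisted prediction. Validation lines are predicted
# jointly with the training lines through the mixed-model equations (the
# random-effect vector spans all lines in K; only training lines carry
# observations), which is exact under the model and equivalent to the
# K_vt-projection formulation.

gebvTable <- function(lines, values, model, trait = NA_character_,
                      training = NULL) {
  structure(data.frame(line = lines, trait = trait, model = model,
                       value = unname(values), row.names = NULL),
            trainingLines = training, class = c("gebvTable", "data.frame"))
}

#' Genomic BLUP prediction
#'
#' Fits y = 1 mu + u_G + r on the training lines with u_G ~ N(0, K sigma2_uG)
#' over all lines in K, and returns predicted values mu + u for the requested
#' validation lines.
#'
#' @param trainBlues named numeric vector (or BLUE table) of training-line
#'   phenotypic BLUEs.
#' @param K genomic relationship matrix covering training and validation
#'   lines.
#' @param validationLines line identifiers to predict (default: all non-training
#'   lines in K).
#' @param trait optional trait tag carried through to the output.
#' @return \code{gebvTable} data.frame (line, trait, model, value); attribute
#'   \code{fit} holds the underlying \code{remlFit}, \code{gv} the centered
#'   genetic effects.
#' @export
gblupPredict <- function(trainBlues, K, validationLines = NULL, trait = NA) {
  y <- asBlueVector(trainBlues)
  train <- names(y)
  if (!all(train %in% rownames(K))) stop("training lines missing from K")
  if (is.null(validationLines)) validationLines <- setdiff(rownames(K), train)
  if (!all(validationLines %in% rownames(K)))
    stop("validation line absent from K: ",
         paste(setdiff(validationLines, rownames(K)), collapse = ", "))
  Z <- incidence(train, rownames(K))
  fit <- fitREML(y, NULL, list(g = list(Z = Z, K = K)))
  u <- fit$blups$g
  pred <- fit$beta[1] + u[validationLines]
  out <- gebvTable(validationLines, pred, "GS", trait, train)
  attr(out, "fit") <- fit
  attr(out, "gv") <- u
  out
}

incidence <- function(rows, allIds) {
  Z <- matrix(0, length(rows), length(allIds),
              dimnames = list(rows, allIds))
  Z[cbind(seq_along(rows), match(rows, allIds))] <- 1
  Z
}

#' Weighted GBLUP with a fixed haploblock effect
#'
#' As \code{\link{gblupPredict}} but upweighting a major locus by fitting its
#' haploblock codes as a fixed effect: y = 1 mu + M_hb beta + u_G + r.
#' Validation predictions combine the fixed haploblock term with the
#' kinship-propagated genetic effect.
#'
#' @inheritParams gblupPredict
#' @param haploblock a \linkS4class{Haploblock} with codes for all lines.
#' @return \code{gebvTable} with model tag \code{"wGS"}.
#' @export
wblupPredict <- function(trainBlues, K, haploblock, validationLines = NULL,
                         trait = NA) {
  y <- asBlueVector(trainBlues)
  train <- names(y)
  if (!all(train %in% rownames(K))) stop("training lines missing from K")
  if (is.null(validationLines)) validationLines <- setdiff(rownames(K), train)
  if (!all(validationLines %in% rownames(K)))
    stop("validation line absent from K")
  hb <- blockCodes(haploblock)
  if (!all(c(train, validationLines) %in% names(hb)))
    stop("haploblock codes missing for some lines")
  if (var(hb[train]) < 1e-24)
    stop("haploblock is monomorphic in the training set; fixed effect inestimable")
  X <- cbind(`(Intercept)` = 1, hb = hb[train])
  Z <- incidence(train, rownames(K))
  fit <- fitREML(y, X, list(g = list(Z = Z, K = K)))
  u <- fit$blups$g
  pred <- fit$beta["(Intercept)"] + hb[validationLines] * fit$beta["hb"] +
    u[validationLines]
  out <- gebvTable(validationLines, pred, "wGS", trait, train)
  attr(out, "fit") <- fit
  out
}

#' Ridge-regression BLUP marker-assisted prediction
#'
#' y = 1 mu + Z_M u_M + r with iid marker effects u_M ~ N(0, I sigma2_uM).
#' Effects are estimated on the training lines and applied to the validation
#' lines' marker scores.
#'
#' @inheritParams gblupPredict
#' @param geno complete \linkS4class{GenotypeData} covering all lines.
#' @param markers marker identifiers to use (default: all markers in
#'   \code{geno}).
#' @return list with \code{gebv} (\code{gebvTable}, model \code{"MAS"}) and
#'   \code{markerEffects} (data.frame marker, effect).
#' @export
rrblupPredict <- function(trainBlues, geno, markers = NULL,
                          validationLines = NULL, trait = NA) {
  y <- asBlueVector(trainBlues)
  train <- names(y)
  if (is.null(markers)) markers <- markerIds(geno)
  if (!all(markers %in% markerIds(geno)))
    stop("unknown markers: ", paste(setdiff(markers, markerIds(geno)), collapse = ", "))
  codes <- genoCodes(geno)[, markers, drop = FALSE]
  if (anyNA(codes)) stop("marker codes contain missing calls; impute first")
  if (!all(train %in% rownames(codes))) stop("training lines missing from geno")
  if (is.null(validationLines))
    validationLines <- setdiff(rownames(codes), train)
  Mt <- codes[train, , drop = FALSE]
  fit <- fitREML(y, NULL, list(m = list(Z = Mt, K = NULL)))
  uM <- fit$blups$m
  names(uM) <- markers
  pred <- fit$beta[1] + as.numeric(codes[validationLines, , drop = FALSE] %*% uM)
  out <- gebvTable(validationLines, pred, "MAS", trait, train)
  attr(out, "fit") <- fit
  list(gebv = out, markerEffects = data.frame(marker = markers,
                                              effect = unname(uM)))
}

#' Kinship-corrected genome-wide association scan
#'
#' Per-marker fixed-effect Wald test in y = 1 mu + m alpha + u_G + r with the
#' polygenic term u_G ~ N(0, K sigma2_uG). Variance components are estimated
#' once on the null model (marker excluded) and reused for every marker, the
#' usual population-parameters-previously-determined approximation that makes
#' resampling-embedded scans affordable.
#'
#' @param trainBlues named numeric vector / BLUE table for the training lines.
#' @param geno complete \linkS4class{GenotypeData}.
#' @param K kinship covering the training lines.
#' @return data.frame: marker, chrom, pos, beta, se, stat, p, flag
#'   (monomorphic markers get p = 1 and flag \code{"monomorphic"}).
#' @export
gwasScan <- function(trainBlues, geno, K) {
  y <- asBlueVector(trainBlues)
  train <- names(y)
  if (!all(train %in% lineIds(geno)) || !all(train %in% rownames(K)))
    stop("training lines not covered by geno and K")
  codes <- genoCodes(geno)[train, , drop = FALSE]
  if (anyNA(codes)) stop("genotypes contain missing calls; impute first")
  n <- length(y)
  Ktt <- K[train, train]
  es <- eigen(Ktt, symmetric = TRUE)
  d <- pmax(es$values, 0)
  Q <- es$vectors
  yt <- as.numeric(crossprod(Q, y))
  onet <- as.numeric(crossprod(Q, rep(1, n)))
  # null-model REML via the same profiled spectral likelihood
  nullFit <- fitREML(y, NULL, list(g = list(Z = NULL, K = Ktt)))
  s2u <- nullFit$vc["g"]; s2r <- nullFit$vc["residual"]
  w <- pmax(s2u * d + s2r, 1e-12)
  Mt <- crossprod(Q, codes)
  a11 <- sum(onet^2 / w)
  b1 <- sum(onet * yt / w)
  a12 <- as.numeric(crossprod(Mt / w, onet))
  a22 <- colSums(Mt^2 / w)
  b2 <- as.numeric(crossprod(Mt / w, yt))
  det <- a11 * a22 - a12^2
  mono <- apply(codes, 2, var) < 1e-24
  det[mono] <- NA
  beta <- (a11 * b2 - a12 * b1) / det
  se <- sqrt(a11 / det)
  stat <- beta / se
  p <- 2 * pt(-abs(stat), df = n - 2)
  p[mono] <- 1
  map <- markerMap(geno)
  data.frame(marker = map$marker, chrom = map$chrom, pos = map$pos,
             beta = ifelse(mono, 0, beta), se = ifelse(mono, NA, se),
             stat = ifelse(mono, 0, stat), p = p,
             flag = ifelse(mono, "monomorphic", ""), row.names = NULL)
}

#' Proportion of genetic variance explained by a locus
#'
#' rho_G = max(0, 1 - sigma2G(locus fixed) / sigma2G(base)), where both
#' genetic variances come from REML GBLUP fits sharing all terms except the
#' locus fixed effect.
#'
#' @param trainBlues named numeric vector / BLUE table.
#' @param K kinship matrix covering the training lines.
#' @param locus a \linkS4class{Haploblock}, or a marker id (then \code{geno}
#'   is required), or a named numeric code vector.
#' @param geno optional \linkS4class{GenotypeData} when \code{locus} is a
#'   marker id.
#' @return list with \code{rhoG}, \code{sigma2G_base}, \code{sigma2G_fixed},
#'   \code{locus}.
#' @export
varianceExplained <- function(trainBlues, K, locus, geno = NULL) {
  y <- asBlueVector(trainBlues)
  train <- names(y)
  codes <- if (is(locus, "Haploblock")) blockCodes(locus)
           else if (is.character(locus)) {
             if (is.null(geno)) stop("geno required when locus is a marker id")
             if (!locus %in% markerIds(geno)) stop("unknown marker id: ", locus)
             setNames(genoCodes(geno)[, locus], lineIds(geno))
           } else locus
  locusName <- if (is(locus, "Haploblock")) locus@name
               else if (is.character(locus)) locus else "locus"
  if (!all(train %in% names(codes))) stop("locus codes missing for training lines")
  x <- codes[train]
  if (var(x) < 1e-24) stop("locus monomorphic in the training set")
  Ktt <- K[train, train]
  base <- fitREML(y, NULL, list(g = list(Z = NULL, K = Ktt)))
  s2base <- unname(base$vc["g"])
  if (s2base < 1e-10 * var(y))
    stop("base genetic variance is ~0; rho_G undefined")
  X <- cbind(`(Intercept)` = 1, locus = x)
  fixed <- fitREML(y, X, list(g = list(Z = NULL, K = Ktt)))
  s2fix <- unname(fixed$vc["g"])
  list(rhoG = max(0, 1 - s2fix / s2base), sigma2G_base = s2base,
       sigma2G_fixed = s2fix, locus = locusName)
}
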