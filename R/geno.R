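# Genotype curation: QC -> chromosome-wise kNN imputation -> perfect-LD
# de-duplication, plus haploblock coding, the VanRaden genomic relationship
# matrix and kinship PCA.

#' Marker quality control
#'
#' Removes markers with a minor allele frequency below \code{mafMin}
#' (computed on non-missing calls) or with a missing-call fraction strictly
#' above \code{missMax}.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param mafMin minimum minor allele frequency kept (default 0.10).
#' @param missMax maximum tolerated missing fraction (default 0.10, strict
#'   \code{>} removal so exactly 10\% missing is kept).
#' @return list with \code{geno} (filtered) and \code{report} (data.frame
#'   marker, reason, value for every removal).
#' @export
qcFilter <- function(geno, mafMin = 0.10, missMax = 0.10) {
  p <- alleleFreqs(geno)
  maf <- pmin(p, 1 - p)
  missFrac <- colMeans(is.na(genoCodes(geno)))
  badMaf <- maf < mafMin - 1e-12
  badMiss <- missFrac > missMax + 1e-12
  report <- rbind(
    data.frame(marker = markerIds(geno)[badMaf],
               reason = rep("maf", sum(badMaf)),
               value = unname(maf[badMaf]), row.names = NULL),
    data.frame(marker = markerIds(geno)[badMiss & !badMaf],
               reason = rep("missing", sum(badMiss & !badMaf)),
               value = unname(missFrac[badMiss & !badMaf]), row.names = NULL))
  keep <- !(badMaf | badMiss)
  if (!any(keep)) stop("quality control removed every marker")
  list(geno = geno[, which(keep)], report = report)
}

#' Chromosome-wise k-nearest-neighbour imputation
#'
#' Deterministic iterative kNN: per chromosome, line-to-line distances are
#' mean absolute code differences over shared non-missing markers; each
#' missing call is replaced by the modal code of the k nearest lines observed
#' at that marker (ties resolved by the single nearest neighbour). After the
#' first sweep completes the matrix, further sweeps re-impute the originally
#' missing cells using distances on the completed data.
#'
#' @param geno a \linkS4class{GenotypeData} (post-QC; a marker with all calls
#'   missing raises an error).
#' @param k number of neighbours (default 5).
#' @param sweeps refinement sweeps (default 3).
#' @return imputed \linkS4class{GenotypeData}; observed entries unchanged.
#' @export
imputeGenotypes <- function(geno, k = 5, sweeps = 3) {
  codes <- genoCodes(geno)
  if (!anyNA(codes)) return(geno)
  if (any(colSums(!is.na(codes)) == 0))
    stop("marker with all calls missing; run qcFilter first")
  map <- markerMap(geno)
  for (cc in unique(map$chrom)) {
    idx <- which(map$chrom == cc)
    sub <- codes[, idx, drop = FALSE]
    missCells <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(missCells) == 0) next
    cur <- sub
    for (sw in seq_len(sweeps)) {
      D <- as.matrix(dist(cur, method = "manhattan")) / ncol(cur)
      filled <- cur
      for (r in seq_len(nrow(missCells))) {
        i <- missCells[r, 1]; j <- missCells[r, 2]
        donors <- if (sw == 1) which(!is.na(sub[, j])) else seq_len(nrow(sub))
        donors <- setdiff(donors, i)
        dvals <- if (sw == 1) sub[donors, j] else cur[donors, j]
        ok <- !is.na(dvals) & is.finite(D[i, donors])
        donors <- donors[ok]; dvals <- dvals[ok]
        if (length(donors) == 0) { filled[i, j] <- 0; next }
        ord <- order(D[i, donors], donors)
        nn <- ord[seq_len(min(k, length(ord)))]
        tab <- table(dvals[nn])
        top <- names(tab)[tab == max(tab)]
        filled[i, j] <- if (length(top) == 1) as.numeric(top)
                        else dvals[ord[1]]
      }
      cur <- filled
      if (anyNA(cur)) cur[is.na(cur)] <- 0
    }
    codes[, idx] <- cur
  }
  GenotypeData(codes, map)
}

#' Drop markers in perfect linkage disequilibrium
#'
#' Among each clique of markers with pairwise squared correlation of exactly
#' 1 (within 1e-12), all but one randomly chosen representative are dropped.
#' Monomorphic markers (undefined correlation) are dropped with reason
#' \code{"monomorphic"}.
#'
#' @param geno a complete (imputed) \linkS4class{GenotypeData}.
#' @param seed integer seed for the random representative choice.
#' @return list with \code{geno} and \code{dropped} (data.frame marker,
#'   reason, keptAs).
#' @export
dedupPerfectLD <- function(geno, seed = 1) {
  codes <- genoCodes(geno)
  if (anyNA(codes)) stop("dedupPerfectLD requires complete data; impute first")
  mono <- apply(codes, 2, function(v) var(v) < 1e-24)
  dropped <- data.frame(marker = markerIds(geno)[mono],
                        reason = rep("monomorphic", sum(mono)),
                        keptAs = rep(NA_character_, sum(mono)))
  poly <- which(!mono)
  sub <- codes[, poly, drop = FALSE]
  cm <- suppressWarnings(cor(sub))
  hit <- which(cm^2 >= 1 - 1e-12 & upper.tri(cm), arr.ind = TRUE)
  keepFlag <- rep(TRUE, length(poly))
  if (nrow(hit) > 0) {
    # union-find over perfect-LD pairs
    parent <- seq_along(poly)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (r in seq_len(nrow(hit))) {
      a <- find(hit[r, 1]); b <- find(hit[r, 2])
      if (a != b) parent[b] <- a
    }
    roots <- vapply(seq_along(poly), find, 0L)
    withSeed(seed, {
      for (g in unique(roots[duplicated(roots)])) {
        members <- which(roots == g)
        keep <- members[sample.int(length(members), 1)]
        out <- setdiff(members, keep)
        keepFlag[out] <- FALSE
        dropped <- rbind(dropped, data.frame(
          marker = colnames(sub)[out], reason = "r2=1",
          keptAs = colnames(sub)[keep]))
      }
    })
  }
  list(geno = geno[, poly[keepFlag]], dropped = dropped)
}

#' Build a two-SNP haploblock
#'
#' Codes each line +1 when both component markers are homozygous for their
#' tolerance allele, -1 when both are homozygous for the susceptibility
#' allele, and 0 otherwise (recombinant or heterozygous combinations).
#'
#' @param geno a complete \linkS4class{GenotypeData}.
#' @param markerA,markerB component marker identifiers.
#' @param favorable numeric length-2 (+1/-1): the homozygous code carrying the
#'   tolerance allele at each component marker.
#' @param name haploblock label.
#' @return A \linkS4class{Haploblock}.
#' @export
buildHaploblock <- function(geno, markerA, markerB, favorable = c(1, 1),
                            name = "CNV") {
  for (m in c(markerA, markerB))
    if (!m %in% markerIds(geno)) stop("unknown marker id: ", m)
  a <- genoCodes(geno)[, markerA]
  b <- genoCodes(geno)[, markerB]
  if (anyNA(a) || anyNA(b)) stop("component markers contain missing calls; impute first")
  a <- a * favorable[1]
  b <- b * favorable[2]
  code <- ifelse(a == 1 & b == 1, 1, ifelse(a == -1 & b == -1, -1, 0))
  new("Haploblock", name = name, markerA = markerA, markerB = markerB,
      favorable = setNames(as.numeric(favorable), c(markerA, markerB)),
      codes = setNames(code, lineIds(geno)))
}

#' VanRaden genomic relationship matrix
#'
#' \eqn{K = W W' / (2 \sum_k p_k (1 - p_k))} with \eqn{W_{ik} = Z_{ik} + 1 -
#' 2 p_k} the column-centered marker scores. Rows and columns of K sum to
#' zero when the allele frequencies are computed from the same data.
#'
#' @param geno a complete \linkS4class{GenotypeData}.
#' @param alleleFreq optional frozen allele-frequency vector (e.g. from a
#'   training set) used for centering and scaling; defaults to frequencies of
#'   \code{geno} itself.
#' @return N x N symmetric relationship matrix with line dimnames.
#' @export
computeGRM <- function(geno, alleleFreq = NULL) {
  codes <- genoCodes(geno)
  if (anyNA(codes)) stop("computeGRM requires complete data; impute first")
  p <- if (is.null(alleleFreq)) alleleFreqs(geno) else alleleFreq
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: zero GRM denominator")
  W <- sweep(codes, 2, 2 * p - 1)
  K <- tcrossprod(W) / denom
  dimnames(K) <- list(lineIds(geno), lineIds(geno))
  K
}

#' Principal component analysis of a kinship matrix
#'
#' Eigen-decomposition of K; scores are eigenvectors scaled by the square
#' root of their eigenvalues, variance fractions are eigenvalues (negative
#' values truncated at zero) over their total.
#'
#' @param K kinship matrix.
#' @param nComponents number of components to return (<= nrow(K)).
#' @return list with \code{scores} (N x nComponents), \code{varFrac} (all
#'   components), and \code{values}.
#' @export
kinshipPCA <- function(K, nComponents = 2) {
  N <- nrow(K)
  if (nComponents > N) stop("nComponents exceeds the number of lines")
  es <- eigen(K, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  scores <- es$vectors[, seq_len(nComponents), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(nComponents)]), nComponents)
  rownames(scores) <- rownames(K)
  colnames(scores) <- paste0("PC", seq_len(nComponents))
  list(scores = scores, varFrac = if (sum(lam) > 0) lam / sum(lam) else lam,
       values = es$values)
}
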