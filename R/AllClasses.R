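#' @import methods
#' @importFrom stats cor cov lm.fit optimize optim pnorm pt rnorm runif sd var
#'   model.matrix aggregate setNames cor.test resid complete.cases dist
#' @importFrom utils write.table read.table write.csv read.csv packageVersion
#'   head
#' @importFrom graphics boxplot
#' @importFrom yaml read_yaml
NULL

#' Genotype matrix with marker map
#'
#' Container for biallelic SNP calls on inbred breeding lines. Codes follow
#' the usual \{-1, 0, +1\} convention (the two homozygote classes at -1/+1,
#' heterozygotes at 0) with \code{NA} for missing calls. The marker map gives
#' chromosome and position for every marker.
#'
#' @slot codes numeric matrix, lines x markers, values in \{-1, 0, +1, NA\};
#'   rownames are line identifiers, colnames marker identifiers.
#' @slot map data.frame with columns \code{marker}, \code{chrom}, \code{pos},
#'   one row per marker in column order of \code{codes}.
#' @export
setClass("GenotypeData",
  representation(codes = "matrix", map = "data.frame"))

setValidity("GenotypeData", function(object) {
  msg <- character()
  cd <- object@codes
  if (is.null(rownames(cd)) || anyDuplicated(rownames(cd)))
    msg <- c(msg, "line identifiers (rownames) must be present and unique")
  if (is.null(colnames(cd)) || anyDuplicated(colnames(cd)))
    msg <- c(msg, "marker identifiers (colnames) must be present and unique")
  bad <- !(cd %in% c(-1, 0, 1)) & !is.na(cd)
  if (any(bad)) msg <- c(msg, "genotype codes must be in {-1, 0, +1, NA}")
  mp <- object@map
  if (!all(c("marker", "chrom", "pos") %in% names(mp)))
    msg <- c(msg, "map needs columns marker, chrom, pos")
  else if (!identical(as.character(mp$marker), colnames(cd)))
    msg <- c(msg, "map rows must match marker columns exactly and in order")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param codes lines x markers matrix coded \{-1, 0, +1, NA\} with dimnames.
#' @param map data.frame with columns \code{marker}, \code{chrom}, \code{pos}
#'   matching the columns of \code{codes}.
#' @return A \linkS4class{GenotypeData} object.
#' @export
GenotypeData <- function(codes, map) {
  map$marker <- as.character(map$marker)
  new("GenotypeData", codes = as.matrix(codes), map = map)
}

#' @describeIn GenotypeData-class number of lines
#' @param x,object a \code{GenotypeData}
#' @export
nLines <- function(x) nrow(x@codes)

#' @describeIn GenotypeData-class number of markers
#' @export
nMarkers <- function(x) ncol(x@codes)

#' @describeIn GenotypeData-class line identifiers
#' @export
lineIds <- function(x) rownames(x@codes)

#' @describeIn GenotypeData-class marker identifiers
#' @export
markerIds <- function(x) colnames(x@codes)

#' @describeIn GenotypeData-class raw code matrix
#' @export
genoCodes <- function(x) x@codes

#' @describeIn GenotypeData-class marker map
#' @export
markerMap <- function(x) x@map

#' Allele frequencies of the +1-coded allele
#'
#' Frequency p_k of the +1-coded allele per marker, counting heterozygotes as
#' half, computed on non-missing calls.
#'
#' @param x a \linkS4class{GenotypeData}
#' @return named numeric vector of length \code{nMarkers(x)}
#' @export
alleleFreqs <- function(x) colMeans((x@codes + 1) / 2, na.rm = TRUE)

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nLines(object), "lines x", nMarkers(object), "markers on",
      length(unique(object@map$chrom)), "chromosomes;",
      sprintf("%.2f%% missing\n", 100 * mean(is.na(object@codes))))
})

#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nLines(x))
  if (missing(j)) j <- seq_len(nMarkers(x))
  if (is.character(j)) j <- match(j, markerIds(x))
  GenotypeData(x@codes[i, j, drop = FALSE], x@map[j, , drop = FALSE])
})

#' Two-SNP haploblock tagging a multi-allelic locus
#'
#' Composite marker built from two component SNPs flanking a copy-number
#' variable locus (e.g. the CBF cluster at \emph{Fr-A2}). A line is coded
#' homozygous (+1 favorable, -1 unfavorable) only when both component markers
#' carry the same allele class; any mixed or heterozygous combination is coded
#' 0.
#'
#' @slot name haploblock label
#' @slot markerA,markerB component marker identifiers
#' @slot favorable named numeric (+1/-1) per component marker: which homozygous
#'   code carries the tolerance allele
#' @slot codes named per-line haploblock codes in \{-1, 0, +1\}
#' @export
setClass("Haploblock",
  representation(name = "character", markerA = "character",
                 markerB = "character", favorable = "numeric",
                 codes = "numeric"))

setValidity("Haploblock", function(object) {
  if (!all(object@codes %in% c(-1, 0, 1))) return("block codes must be in {-1,0,+1}")
  if (is.null(names(object@codes))) return("codes must be named by line")
  if (!all(object@favorable %in% c(-1, 1))) return("favorable allele spec must be +1/-1")
  TRUE
})

#' @describeIn Haploblock-class per-line haploblock codes
#' @param x a \code{Haploblock}
#' @export
blockCodes <- function(x) x@codes

setMethod("show", "Haploblock", function(object) {
  cat("Haploblock", object@name, "=", object@markerA, "x", object@markerB, "\n")
  print(table(factor(object@codes, levels = c(-1, 0, 1))))
})

#' Simulated breeding population
#'
#' Output of \code{\link{simulatePopulation}}: genotypes (with injected
#' missingness), the complete error-free codes used to define the genetic
#' truth, true breeding values for the two traits, the latent copy-number
#' state at the planted major locus, per-marker additive effects, and the
#' variance-component truth used by parameter-recovery tests.
#'
#' @slot genotypes \linkS4class{GenotypeData} as observed (missing calls NA)
#' @slot truthCodes complete codes matrix (no missingness)
#' @slot tbv lines x 2 matrix of true breeding values (winter, frost)
#' @slot cnvState integer copy number (1-3) per line at the major locus
#' @slot qtlEffects markers x 2 matrix of realized additive marker effects
#' @slot majorLocus list: chromosome, tag marker ids, favorable allele spec,
#'   per-trait major-locus effect scale
#' @slot varianceTruth list of true variance components and trait covariance
#' @slot phenotypes list of simulated phenotype tables (filled by the trial
#'   simulators / pipeline)
#' @slot config the generating \code{simConfig} list
#' @export
setClass("SimPopulation",
  representation(genotypes = "GenotypeData", truthCodes = "matrix",
                 tbv = "matrix", cnvState = "integer", qtlEffects = "matrix",
                 majorLocus = "list", varianceTruth = "list",
                 phenotypes = "list", config = "list"))

#' @describeIn SimPopulation-class true breeding values (lines x traits)
#' @param x,object a \code{SimPopulation}
#' @export
trueBreedingValues <- function(x) x@tbv

#' @describeIn SimPopulation-class genotype container
#' @export
genotypes <- function(x) x@genotypes

setMethod("show", "SimPopulation", function(object) {
  vt <- object@varianceTruth
  cat("SimPopulation:", nLines(object@genotypes), "lines,",
      nMarkers(object@genotypes), "markers\n")
  cat("  major locus on chr", object@majorLocus$chrom,
      "tagged by", paste(object@majorLocus$tags, collapse = ", "), "\n")
  cat(sprintf("  sigma2G winter %.3f frost %.3f, rG %.2f, major rho %.2f\n",
      vt$sigma2G["winter"], vt$sigma2G["frost"], vt$geneticCorrelation,
      vt$majorQtlRho))
})

# run code with a local, restored RNG state (full determinism contract)
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
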