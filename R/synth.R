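# Synthetic breeding-population generator. Emulates the statistical structure
# of a commercial winter-wheat program: families of inbred lines descended
# from a small founder-haplotype pool (giving realistic kinship heterogeneity
# and within-chromosome LD), a multi-allelic copy-number locus of major effect
# on frost tolerance tagged imperfectly by two flanking SNPs, an oligogenic
# polygenic background shared between two genetically correlated traits, and
# replicated / partially replicated trial phenotypes.

#' Configuration for the population simulator
#'
#' Defaults reproduce the conditions of a wheat breeding program in which the
#' pipeline was designed to operate: 504 lines from 311 crosses, 21
#' chromosomes with 67 SNPs each (about 1,400 markers after QC), a major
#' copy-number locus explaining 20\% of the genetic variance of frost
#' tolerance, entry-mean heritabilities of 0.71 (field winter hardiness,
#' scored 1-9, lower = better) and 0.98 (chamber frost damage percentage,
#' lower = better), and a genetic correlation of 0.6 between the two traits.
#'
#' @param n_lines number of breeding lines (>= 2, >= \code{n_families}).
#' @param n_families number of crosses the lines descend from.
#' @param n_chromosomes,markers_per_chromosome marker panel dimensions.
#' @param major_qtl_rho fraction of genetic variance at the major locus, in
#'   [0,1] (both traits).
#' @param h2_winter,h2_frost entry-mean heritabilities in [0,1] used when
#'   simulating trials.
#' @param genetic_correlation correlation of true breeding values between the
#'   two traits, in [-1,1].
#' @param maf_range ordered pair of founder minor-allele-frequency bounds in
#'   (0, 0.5].
#' @param missing_rate fraction of genotype calls set missing.
#' @param seed integer seed; same seed gives a bit-identical population.
#' @param n_qtl number of polygenic background QTL per trait (placed on shared
#'   marker positions). An oligogenic architecture is assumed: frost tolerance
#'   and winter hardiness are influenced by a moderate number of loci spread
#'   over many chromosomes.
#' @param n_founders founder haplotypes in the base pool.
#' @param segments_per_chromosome recombination blocks per chromosome used for
#'   the mosaic inheritance model.
#' @param tag_concordance per-haplotype probability that each tag SNP carries
#'   the allele matching the causal copy-number class (imperfect tagging).
#' @param residual_het residual heterozygosity rate of the inbred lines.
#' @param major_chromosome chromosome carrying the major locus (5, for a
#'   Fr-A2-like locus on the group-5 chromosome).
#' @param trait_means,genetic_sd named (winter, frost) trait means and genetic
#'   standard deviations on the observation scales (1-9 score; percent).
#' @param cnv_freq founder frequencies of the 1/2/3-copy alleles.
#' @param cnv_effects additive effect pattern over 1/2/3 copies before
#'   scaling; more copies confer tolerance (lower trait values), with
#'   diminishing returns beyond two copies.
#' @return validated configuration list of class \code{simConfig}.
#' @export
simConfig <- function(n_lines = 504, n_families = 311, n_chromosomes = 21,
                      markers_per_chromosome = 67, major_qtl_rho = 0.20,
                      h2_winter = 0.71, h2_frost = 0.98,
                      genetic_correlation = 0.6, maf_range = c(0.10, 0.50),
                      missing_rate = 0.05, seed = 1, n_qtl = 60,
                      n_founders = 16, segments_per_chromosome = 3,
                      tag_concordance = 0.95, residual_het = 0.02,
                      major_chromosome = 5,
                      trait_means = c(winter = 4.5, frost = 50),
                      genetic_sd = c(winter = 1.3, frost = 20),
                      cnv_freq = c(0.3, 0.4, 0.3),
                      cnv_effects = c(0, -1, -1.2)) {
  cfg <- as.list(environment())
  stopifnot(n_lines >= 2, markers_per_chromosome >= 1, n_chromosomes >= 1,
            n_families >= 1, segments_per_chromosome >= 1, n_founders >= 2)
  if (n_lines < n_families) stop("n_lines must be >= n_families")
  frac <- c(major_qtl_rho = major_qtl_rho, h2_winter = h2_winter,
            h2_frost = h2_frost, missing_rate = missing_rate,
            tag_concordance = tag_concordance, residual_het = residual_het)
  if (any(frac < 0 | frac > 1))
    stop("fractions must lie in [0,1]: ",
         paste(names(frac)[frac < 0 | frac > 1], collapse = ", "))
  if (abs(genetic_correlation) > 1) stop("genetic_correlation must be in [-1,1]")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be ordered and within (0, 0.5]")
  if (!major_chromosome %in% seq_len(n_chromosomes))
    stop("major_chromosome outside the simulated genome")
  if (n_qtl > n_chromosomes * markers_per_chromosome - 2)
    stop("n_qtl exceeds the number of available markers")
  structure(cfg, class = "simConfig")
}

# scale a centered vector to unit sample standard deviation
unitScale <- function(v) {
  v <- v - mean(v)
  s <- sd(v)
  if (s < 1e-12) stop("degenerate (constant) component in TBV calibration")
  v / s
}

#' Simulate a breeding population
#'
#' Draws founder haplotypes, builds parents as founder mosaics, derives inbred
#' offspring family-wise by segment inheritance, plants a multi-allelic
#' copy-number locus with two flanking tag SNPs, and constructs true breeding
#' values for winter hardiness and frost tolerance that hit the configured
#' genetic variances, genetic correlation, and major-locus variance fraction
#' exactly in the realized sample (Gram-Schmidt calibration of the realized
#' genetic components).
#'
#' @param config a \code{\link{simConfig}} list.
#' @return A \linkS4class{SimPopulation}.
#' @export
simulatePopulation <- function(config) {
  if (!inherits(config, "simConfig")) config <- do.call(simConfig, config)
  withSeed(config$seed, simulatePopulationImpl(config))
}

simulatePopulationImpl <- function(cfg) {
  nc <- cfg$n_chromosomes; mpc <- cfg$markers_per_chromosome
  M <- nc * mpc; N <- cfg$n_lines; H <- cfg$n_founders
  chrom <- rep(seq_len(nc), each = mpc)
  posIdx <- rep(seq_len(mpc), nc)
  markers <- sprintf("S%d_%03d", chrom, posIdx)
  map <- data.frame(marker = markers, chrom = chrom, pos = posIdx,
                    stringsAsFactors = FALSE)

  # founder haplotype pool with frequencies held inside the configured bounds
  maf <- runif(M, cfg$maf_range[1], cfg$maf_range[2])
  f <- ifelse(runif(M) < 0.5, maf, 1 - maf)
  loC <- ceiling(H * cfg$maf_range[1])
  hiC <- floor(H * (1 - cfg$maf_range[1]))
  cnt <- pmin(pmax(round(H * f), loC), hiC)
  founders <- matrix(0L, H, M)
  for (k in seq_len(M)) founders[sample.int(H, cnt[k]), k] <- 1L

  # major locus: copy-number allele per founder haplotype plus two tag SNPs
  segBreaks <- lapply(seq_len(nc), function(cc) {
    idx <- which(chrom == cc)
    split(idx, cut(seq_along(idx), cfg$segments_per_chromosome, labels = FALSE))
  })
  # the two tag SNPs must sit in one inheritance segment so they travel with
  # the causal copy-number state; use the longest segment, centrally placed
  majorSegs <- segBreaks[[cfg$major_chromosome]]
  lens <- vapply(majorSegs, length, 0L)
  if (max(lens) < 2)
    stop("major chromosome too short for two tag SNPs; ",
         "reduce segments_per_chromosome or add markers")
  majorSegIdx <- majorSegs[[which.max(lens)]]
  mid <- max(1, ceiling(length(majorSegIdx) / 2) - 1)
  tagIdx <- majorSegIdx[c(mid, mid + 1)]
  cnvAllele <- sample(1:3, H, replace = TRUE, prob = cfg$cnv_freq)
  if (length(unique(cnvAllele >= 2)) == 1) cnvAllele[1:2] <- c(1L, 3L)
  for (t in tagIdx) {
    tag <- as.integer(cnvAllele >= 2)
    flip <- runif(H) > cfg$tag_concordance
    founders[, t] <- ifelse(flip, 1L - tag, tag)
  }

  # parents as founder mosaics; two parental haplotypes per family
  nPar <- 2L * cfg$n_families
  parentHap <- matrix(0L, nPar, M)
  parentCNV <- integer(nPar)
  segList <- unlist(segBreaks, recursive = FALSE)
  parentSegFounder <- matrix(sample.int(H, nPar * length(segList), replace = TRUE),
                             nPar, length(segList))
  majorSegPos <- which(vapply(segList, function(s) tagIdx[1] %in% s, NA))
  for (s in seq_along(segList)) {
    idx <- segList[[s]]
    parentHap[, idx] <- founders[parentSegFounder[, s], idx, drop = FALSE]
  }
  parentCNV <- cnvAllele[parentSegFounder[, majorSegPos]]

  # offspring: per segment inherit (doubled) one parental haplotype; a small
  # residual-heterozygosity rate mixes both parental haplotypes in a segment
  fam <- sort(rep_len(seq_len(cfg$n_families), N))
  codes <- matrix(0, N, M, dimnames = list(sprintf("L%03d", seq_len(N)), markers))
  cnvState <- integer(N)
  for (s in seq_along(segList)) {
    idx <- segList[[s]]
    pick <- ifelse(runif(N) < 0.5, 2L * fam - 1L, 2L * fam)
    het <- runif(N) < cfg$residual_het
    prim <- parentHap[pick, idx, drop = FALSE]
    codes[, idx] <- 2 * prim - 1
    if (any(het)) {
      other <- ifelse(pick %% 2L == 1L, pick + 1L, pick - 1L)
      sec <- parentHap[other[het], idx, drop = FALSE]
      codes[het, idx] <- prim[het, , drop = FALSE] + sec - 1
    }
    if (s == majorSegPos) cnvState <- parentCNV[pick]
  }

  # oligogenic background effects on shared QTL positions
  qtlPos <- sample(setdiff(seq_len(M), tagIdx), cfg$n_qtl)
  B <- matrix(rnorm(cfg$n_qtl * 2), cfg$n_qtl, 2)
  poly <- codes[, qtlPos, drop = FALSE] %*% B

  # calibrate TBVs exactly: var = sigma2G, cor = rg, major fraction = rho
  rho <- cfg$major_qtl_rho
  rg <- cfg$genetic_correlation
  sG <- cfg$genetic_sd[c("winter", "frost")]
  m <- cfg$cnv_effects[cnvState]
  useMajor <- rho > 0 && sd(m) > 1e-12
  if (rho > 0 && !useMajor)
    warning("major locus monomorphic in this draw; major_qtl_rho set to 0")
  if (!useMajor) rho <- 0
  cm <- if (useMajor) unitScale(m) else rep(0, N)
  residOn <- function(v, on) {
    v <- v - mean(v)
    for (b in on) v <- v - sum(v * b) / sum(b * b) * b
    v
  }
  base <- if (useMajor) list(cm) else list()
  e1 <- unitScale(residOn(poly[, 1], base))
  e2perp <- unitScale(residOn(poly[, 2], c(base, list(e1))))
  rhoPP <- if (rho < 1) (rg - rho) / (1 - rho) else 1
  if (abs(rhoPP) > 1) {
    warning("requested genetic_correlation unattainable given major_qtl_rho; clamped")
    rhoPP <- sign(rhoPP)
  }
  e2 <- rhoPP * e1 + sqrt(max(0, 1 - rhoPP^2)) * e2perp
  tbv <- cbind(
    winter = sqrt(rho) * sG["winter"] * cm + sqrt(1 - rho) * sG["winter"] * e1,
    frost  = sqrt(rho) * sG["frost"] * cm + sqrt(1 - rho) * sG["frost"] * e2)
  rownames(tbv) <- rownames(codes)

  # recover realized per-marker effects: TBV columns live in the span of
  # (poly1, poly2, m, 1); project to express them in that basis
  basis <- cbind(poly, if (useMajor) m else NULL, 1)
  gam <- qr.coef(qr(basis), tbv)
  gam[is.na(gam)] <- 0
  qtlEffects <- matrix(0, M, 2, dimnames = list(markers, c("winter", "frost")))
  qtlEffects[qtlPos, ] <- B %*% gam[1:2, , drop = FALSE]
  majorScale <- if (useMajor) gam[3, ] else c(winter = 0, frost = 0)

  obs <- codes
  if (cfg$missing_rate > 0)
    obs[runif(length(obs)) < cfg$missing_rate] <- NA
  geno <- GenotypeData(obs, map)

  vt <- list(sigma2G = setNames(as.numeric(sG^2), c("winter", "frost")),
             covG = rg * prod(sG), geneticCorrelation = rg, majorQtlRho = rho,
             founderFreq = f)
  new("SimPopulation", genotypes = geno, truthCodes = codes, tbv = tbv,
      cnvState = as.integer(cnvState), qtlEffects = qtlEffects,
      majorLocus = list(chrom = cfg$major_chromosome, tags = markers[tagIdx],
                        favorable = setNames(c(1, 1), markers[tagIdx]),
                        effectScale = majorScale),
      varianceTruth = vt, phenotypes = list(), config = unclass(cfg))
}

# residual variance delivering a target entry-mean heritability given the
# realized replication r_eff = plots / lines (h2 floored at 0.01 so a zero
# heritability still yields a finite, effectively uninformative trial)
residVarForH2 <- function(sigma2G, h2, rEff) {
  h2 <- max(h2, 0.01)
  rEff * sigma2G * (1 - h2) / h2
}

#' Simulate a partially replicated field trial
#'
#' Replicated lines appear once in each of two blocks and unreplicated lines
#' are split across the blocks (a partially replicated row-column layout).
#' Observations are TBV + block + row + column + residual with residual
#' variance solving the configured entry-mean heritability under the realized
#' replication. Winter-hardiness values are mapped to the 1-9 scoring scale
#' (1 = very good winter survival) by rounding and clipping; frost values to
#' the 0-100 damage scale.
#'
#' @param pop a \linkS4class{SimPopulation}.
#' @param trait \code{"winter"} or \code{"frost"}.
#' @param n_replicated,n_unreplicated numbers of two-plot and single-plot
#'   lines (sum must not exceed the population size).
#' @param seed integer seed for line sampling, layout and noise.
#' @param trial trial label.
#' @param block_sd,row_sd,col_sd standard deviations of the random design
#'   effects; \code{block_sd = NULL} defaults to 0.4 genetic SD.
#' @param h2 heritability override; defaults to the configured value for the
#'   trait.
#' @param lines optional pool of line ids to draw the trial entries from
#'   (default: the whole population).
#' @return long-format data.frame: line, trial, block, row, column, trait,
#'   value.
#' @export
simulateFieldTrial <- function(pop, trait = c("winter", "frost"), n_replicated,
                               n_unreplicated, seed, trial = "T1",
                               block_sd = NULL, row_sd = 0, col_sd = 0,
                               h2 = NULL, lines = NULL) {
  trait <- match.arg(trait)
  cfg <- pop@config
  pool <- if (is.null(lines)) rownames(pop@tbv) else lines
  if (n_replicated + n_unreplicated > length(pool))
    stop("n_replicated + n_unreplicated exceeds the number of lines")
  sG2 <- cfg$genetic_sd[[trait]]^2
  if (is.null(h2)) h2 <- if (trait == "winter") cfg$h2_winter else cfg$h2_frost
  if (is.null(block_sd)) block_sd <- 0.4 * cfg$genetic_sd[[trait]]
  withSeed(seed, {
    lines <- sample(pool, n_replicated + n_unreplicated)
    repl <- lines[seq_len(n_replicated)]
    unrep <- setdiff(lines, repl)
    half <- seq_len(ceiling(length(unrep) / 2))
    entries <- rbind(
      data.frame(line = c(repl, unrep[half]), block = "B1"),
      data.frame(line = c(repl, unrep[-half]), block = "B2"))
    nPlots <- nrow(entries)
    rEff <- nPlots / length(lines)
    s2e <- residVarForH2(sG2, h2, rEff)
    # score rounding itself contributes ~1/12 noise variance; discount it
    if (trait == "winter" && s2e > 0) s2e <- max(s2e - 1 / 12, 0.01 * sG2)
    out <- do.call(rbind, lapply(split(entries, entries$block), function(bl) {
      nb <- nrow(bl)
      ncol_ <- ceiling(sqrt(nb))
      ord <- sample.int(nb)
      bl <- bl[ord, , drop = FALSE]
      bl$row <- ((seq_len(nb) - 1) %/% ncol_) + 1
      bl$column <- ((seq_len(nb) - 1) %% ncol_) + 1
      bl
    }))
    rownames(out) <- NULL
    blockEff <- setNames(rnorm(2, 0, block_sd), c("B1", "B2"))
    rowLev <- unique(out[c("block", "row")])
    colLev <- unique(out[c("block", "column")])
    rowEff <- setNames(rnorm(nrow(rowLev), 0, row_sd),
                       paste(rowLev$block, rowLev$row))
    colEff <- setNames(rnorm(nrow(colLev), 0, col_sd),
                       paste(colLev$block, colLev$column))
    val <- cfg$trait_means[[trait]] + pop@tbv[out$line, trait] +
      blockEff[out$block] + rowEff[paste(out$block, out$row)] +
      colEff[paste(out$block, out$column)] + rnorm(nPlots, 0, sqrt(s2e))
    out$trait <- trait
    out$value <- if (trait == "winter") pmin(9, pmax(1, round(val)))
                 else pmin(100, pmax(0, val))
    out$trial <- trial
    out[, c("line", "trial", "block", "row", "column", "trait", "value")]
  })
}

#' Simulate a complete-block frost chamber experiment
#'
#' Randomized complete block design: every line in every block, frost damage
#' recorded as a percentage (0-100, truncated at the bounds), residual noise
#' calibrated so the entry-mean heritability matches the configured
#' \code{h2_frost} given the number of blocks.
#'
#' @param pop a \linkS4class{SimPopulation}.
#' @param n_blocks number of complete blocks (>= 2).
#' @param seed integer seed.
#' @param lines optional subset of line ids (default: all lines).
#' @param trial trial label.
#' @param block_sd block-effect standard deviation (percent scale).
#' @param h2 heritability override.
#' @return long-format data.frame as in \code{\link{simulateFieldTrial}}.
#' @export
simulateFrostExperiment <- function(pop, n_blocks = 4, seed, lines = NULL,
                                    trial = "FROST", block_sd = 3, h2 = NULL) {
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  cfg <- pop@config
  if (is.null(lines)) lines <- rownames(pop@tbv)
  if (is.null(h2)) h2 <- cfg$h2_frost
  sG2 <- cfg$genetic_sd[["frost"]]^2
  s2e <- residVarForH2(sG2, h2, n_blocks)
  withSeed(seed, {
    blocks <- paste0("B", seq_len(n_blocks))
    out <- expand.grid(line = lines, block = blocks, stringsAsFactors = FALSE)
    blockEff <- setNames(rnorm(n_blocks, 0, block_sd), blocks)
    ncol_ <- ceiling(sqrt(length(lines)))
    pos <- unlist(lapply(blocks, function(b) sample.int(length(lines))))
    out$row <- ((pos - 1) %/% ncol_) + 1
    out$column <- ((pos - 1) %% ncol_) + 1
    val <- cfg$trait_means[["frost"]] + pop@tbv[out$line, "frost"] +
      blockEff[out$block] + rnorm(nrow(out), 0, sqrt(s2e))
    out$trait <- "frost"
    out$value <- pmin(100, pmax(0, val))
    out$trial <- trial
    out[, c("line", "trial", "block", "row", "column", "trait", "value")]
  })
}
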