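# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

getFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a mid-sized population with curated genotypes, kinship, haploblock and
# frost BLUEs -- the workhorse for prediction / selection / evaluation tests
predFixture <- function() getFixture("pred", function() {
  cfg <- simConfig(n_lines = 160, n_families = 100, markers_per_chromosome = 20,
                   seed = 9)
  pop <- simulatePopulation(cfg)
  qc <- qcFilter(genotypes(pop))
  imp <- imputeGenotypes(qc$geno)
  g <- dedupPerfectLD(imp, seed = 1)$geno
  K <- computeGRM(g)
  tags <- pop@majorLocus$tags
  hb <- buildHaploblock(imp, tags[1], tags[2],
                        favorable = unname(pop@majorLocus$favorable),
                        name = "CNV_S")
  ana <- fitFrostModel(simulateFrostExperiment(pop, 4, seed = 2))
  list(pop = pop, geno = g, imp = imp, K = K, hb = hb, ana = ana,
       blues = setNames(ana$blues$blue, ana$blues$line))
})

# small genotype matrix built by hand for micro-oracle checks
toyGeno <- function(codes, chrom = NULL) {
  M <- ncol(codes)
  if (is.null(colnames(codes))) colnames(codes) <- paste0("m", seq_len(M))
  if (is.null(rownames(codes))) rownames(codes) <- paste0("L", seq_len(nrow(codes)))
  if (is.null(chrom)) chrom <- rep(1, M)
  GenotypeData(codes, data.frame(marker = colnames(codes), chrom = chrom,
                                 pos = seq_len(M)))
}

# vector with exact sample correlation r to a reference, via an orthonormal
# centered basis
exactCorPair <- function(n, r, seed = 1) {
  set.seed(seed)
  z1 <- scale(rnorm(n))[, 1]
  z2 <- resid(lm(rnorm(n) ~ z1))
  z2 <- scale(z2)[, 1]
  list(x = z1, y = r * z1 + sqrt(1 - r^2) * z2)
}

quietly <- function(expr) suppressWarnings(suppressMessages(expr))
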