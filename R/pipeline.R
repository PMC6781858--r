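# End-to-end orchestration: simulate -> phenotypic analysis -> genotype
# curation -> cross-validated prediction -> outputs. Every stage failure is
# re-raised with the stage name; all randomness derives from the single
# config seed so a fixed config reproduces byte-identical tables.

#' Default pipeline configuration
#'
#' Nested list accepted by \code{\link{runPipeline}} (and serialisable as
#' YAML). \code{simulation} holds \code{\link{simConfig}} arguments;
#' \code{experiments} the trial layouts; \code{evaluation} the resampling
#' scheme and model set.
#'
#' @param n_lines,n_replicates convenience overrides for the two knobs most
#'   often reduced for smoke runs.
#' @param seed master seed.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(n_lines = 220, n_replicates = 10, seed = 1) {
  list(
    seed = seed,
    simulation = list(n_lines = n_lines, n_families = max(2, n_lines %/% 2),
                      markers_per_chromosome = 30, seed = seed),
    experiments = list(
      field = list(n_replicated = round(n_lines * 0.4),
                   n_unreplicated = n_lines - round(n_lines * 0.4)),
      frost = list(n_blocks = 4)),
    evaluation = list(n_replicates = n_replicates, n_train = 130,
                      n_validation = 30,
                      models = c("GS", "wGS", "MAS_random")))
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' simulate -> field + frost phenotypes -> two-pass phenotypic analysis ->
#' genotype QC / imputation / LD de-duplication -> kinship + haploblock ->
#' replicated cross-validation of the requested models -> tables written to
#' \code{outDir} (genotypes, phenotypes, BLUEs, heritability summary,
#' per-replicate accuracies, model summary, run log).
#'
#' @param config nested list as from \code{\link{pipelineConfig}}, or a path
#'   to a YAML file with the same structure.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the population, analyses, kinship, and the
#'   \code{accuracyReport}.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  ev <- config$evaluation
  if (is.null(ev$n_validation) || ev$n_validation < 1)
    stop("config field 'evaluation$n_validation' must be >= 1")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1

  pop <- stageTry("simulate", {
    simArgs <- config$simulation %||% list()
    if (is.null(simArgs$seed)) simArgs$seed <- seed
    simulatePopulation(do.call(simConfig, simArgs))
  })
  N <- nLines(pop@genotypes)

  phenoField <- stageTry("phenotype-field", {
    fl <- config$experiments$field
    simulateFieldTrial(pop, "winter", fl$n_replicated, fl$n_unreplicated,
                       seed = seed + 11, trial = "FIELD1")
  })
  phenoFrost <- stageTry("phenotype-frost", {
    fr <- config$experiments$frost
    simulateFrostExperiment(pop, fr$n_blocks %||% 4, seed = seed + 13)
  })

  anaField <- stageTry("pheno-analysis-field",
                       fitTrialModel(phenoField, candidates = list("block")))
  anaFrost <- stageTry("pheno-analysis-frost", fitFrostModel(phenoFrost))

  genoReady <- stageTry("geno-curation", {
    qc <- qcFilter(pop@genotypes)
    imp <- imputeGenotypes(qc$geno)
    dd <- dedupPerfectLD(imp, seed = seed + 17)
    list(geno = dd$geno, imputed = imp, qcReport = qc$report,
         dropped = dd$dropped)
  })
  K <- stageTry("kinship", computeGRM(genoReady$geno))
  # haploblock components come from the imputed panel: LD pruning may drop a
  # tag SNP that duplicates its partner, but the haploblock needs both
  hb <- stageTry("haploblock", {
    tags <- pop@majorLocus$tags
    if (all(tags %in% markerIds(genoReady$imputed)))
      buildHaploblock(genoReady$imputed, tags[1], tags[2],
                      favorable = unname(pop@majorLocus$favorable),
                      name = "CNV_FrA2_S")
    else NULL
  })

  models <- stageTry("model-set", {
    lapply(ev$models, function(m) {
      if (m == "GS") modelSpec("GS")
      else if (m == "wGS") {
        if (is.null(hb)) stop("wGS requested but haploblock tags were lost in QC")
        modelSpec("wGS", haploblock = hb)
      }
      else if (m == "MAS_random") modelSpec("MAS", route = "random")
      else if (m == "MAS_chromwise") modelSpec("MAS", route = "chromwise")
      else if (m == "MAS_genomewide") modelSpec("MAS", route = "genomewide")
      else stop("unknown model: ", m)
    })
  })

  blues <- setNames(anaFrost$blues$blue, anaFrost$blues$line)
  scheme <- cvScheme(nReplicates = ev$n_replicates %||% 10,
                     nTrain = min(ev$n_train %||% 130, N - (ev$n_validation %||% 30)),
                     nValidation = ev$n_validation %||% 30, seed = seed + 23)
  report <- stageTry("cross-validation",
                     crossValidate(blues, genoReady$geno, K, anaFrost$h2,
                                   scheme, models))

  stageTry("write-outputs", {
    writeGenotypes(genoReady$geno, file.path(outDir, "panel"))
    writePhenotypes(rbind(phenoField, phenoFrost),
                    file.path(outDir, "phenotypes.csv"))
    write.csv(anaField$blues, file.path(outDir, "blues_field.csv"),
              row.names = FALSE)
    write.csv(anaFrost$blues, file.path(outDir, "blues_frost.csv"),
              row.names = FALSE)
    write.csv(data.frame(
      experiment = c("field_winter", "frost"),
      h2 = c(anaField$h2, anaFrost$h2),
      sigma2G = c(anaField$sigma2G, anaFrost$sigma2G),
      MVD = c(anaField$MVD, anaFrost$MVD)),
      file.path(outDir, "h2_summary.csv"), row.names = FALSE)
    write.csv(report$accuracies, file.path(outDir, "accuracies.csv"),
              row.names = FALSE)
    write.csv(report$summary, file.path(outDir, "summary.csv"),
              row.names = FALSE)
    writeLines(c(paste("frostGS", as.character(packageVersion("frostGS"))),
                 paste("seed", seed),
                 paste("lines", N),
                 paste("markers_postQC", nMarkers(genoReady$geno))),
               file.path(outDir, "run.log"))
  })
  invisible(list(population = pop, fieldAnalysis = anaField,
                 frostAnalysis = anaFrost, geno = genoReady$geno, K = K,
                 haploblock = hb, report = report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convenience distribution plot of replicate accuracies
#'
#' @param report an \code{accuracyReport}.
#' @param ... passed to \code{boxplot}.
#' @return invisibly, the report.
#' @export
plotAccuracy <- function(report, ...) {
  graphics::boxplot(accuracy ~ model, data = report$accuracies,
                    ylab = "prediction accuracy", xlab = "", las = 2, ...)
  invisible(report)
}
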