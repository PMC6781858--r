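Package: frostGS
Title: Genomic Selection for Winter Hardiness and Frost Tolerance in Wheat Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for genomic selection on winter hardiness and
    frost tolerance in winter wheat breeding populations. Provides a REML
    mixed-model engine (spectral profiled likelihood for single-kernel models,
    low-rank direct optimisation for multi-component models), two-stage
    phenotypic analysis yielding best linear unbiased estimates and entry-mean
    heritabilities, SNP genotype quality control, chromosome-wise k-nearest
    neighbour imputation, VanRaden genomic relationship matrices, haploblock
    coding for copy-number-variation loci such as Fr-A2, GBLUP and weighted
    GBLUP prediction with fixed major-locus effects, ridge-regression BLUP
    marker-assisted prediction, kinship-corrected association scans, two-stage
    stepwise marker pre-selection, a desired-gains genomic selection index, and
    resampling-based evaluation of prediction accuracy. A synthetic
    breeding-population generator with a planted multi-allelic major locus
    tagged by a two-SNP haploblock makes every stage testable without
    proprietary breeding data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'lmm.R'
    'synth.R'
    'io.R'
    'pheno.R'
    'geno.R'
    'predict.R'
    'markersel.R'
    'index.R'
    'evaluate.R'
    'pipeline.R'
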