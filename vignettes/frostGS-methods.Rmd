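---
title: "Genomic selection for winter hardiness and frost tolerance: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection for winter hardiness and frost tolerance: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frostGS)
```

frostGS implements a complete genomic-selection workflow for two traits that
are notoriously hard to phenotype in winter wheat breeding: **field winter
hardiness**, scored 1-9 after winter (1 = dense surviving stand, 9 = complete
winter kill), and **frost tolerance**, measured as the percentage of frost
damage after a controlled freeze test in a growth chamber. Both scales are
lower-is-better. Because real breeding-program data of this kind are
proprietary, the package ships a synthetic-population generator that
reproduces the statistical structure such an analysis faces, so every stage
is testable end to end.

This vignette explains the models, the generator, the tunable parameters,
the numerical choices, and what the included tests do and do not demonstrate
about real data.

## Phenotypic analysis

Each experiment is analysed with a linear mixed model fitted twice (the
standard two-pass scheme):

* **frost chamber (randomized complete blocks)**: `y_ij = mu + g_i + b_j +
  r_ij` with random blocks `b_j` and iid residuals. The line effect `g_i` is
  first random, which yields the genetic variance `sigma2G` by REML; it is
  then refitted fixed, which yields best linear unbiased estimates (BLUEs)
  and their pairwise-difference variances.
* **field trials (partially replicated row-column layouts)**: the same
  scheme, with candidate models {block}, {block+row}, {block+column},
  {block+row+column} (random row/column effects within blocks, iid
  residuals) compared by AIC of the restricted likelihood. Autoregressive
  residual-correlation structures are deliberately out of scope: the
  model-selection workflow is preserved with a simpler candidate family, a
  documented fidelity gap.
* **across trials**: stage-1 BLUEs are combined with fixed trial effects and
  a pooled random effect absorbing trial-by-line interaction and residual.

The entry-mean heritability is `h2 = sigma2G / (sigma2G + MVD/2)`, where MVD
is the mean variance of a difference of the BLUEs, computed exactly from the
fixed-fit coefficient covariance (and verified in the tests against the
brute-force mean over all line pairs). Trials with `h2 <= 0.3` are flagged
as unusable. A common error variance is assumed for replicated and
unreplicated entries.

## The REML engine

All models run through one engine (`fitREML`):

* a **spectral path** for single-kernel models (GBLUP, RR-BLUP, the
  association scan): one eigendecomposition of the random-effect covariance,
  then 1-D profiled optimisation of the variance ratio on the log scale
  (Brent search, tolerance 1e-10);
* a **direct path** for multi-component models (line + block + row +
  column): Nelder-Mead over all log-variances with each likelihood
  evaluation reduced to q x q linear algebra via the Woodbury identity on
  the low-rank random-effect structure, so the cost is driven by the number
  of random levels, not the number of plots.

Variance components are constrained non-negative by the log
parameterisation; boundary estimates are flagged, never silently truncated.
`solveMME` provides an independent route to the same solutions through
Henderson's mixed-model equations in the `u = K a` parametrisation, which is
exact for singular kernels (a centered genomic relationship matrix always
is); the test suite holds the two routes and a dense GLS closed form
together at 1e-8. AIC is `-2 logRL + 2 (number of variance parameters)` and
is only comparable across identical fixed designs -- the package refuses
otherwise, since restricted likelihoods are not comparable across fixed
parts.

## Genotype curation

Markers are filtered (minor allele frequency < 0.10 removed, missingness
strictly above 10% removed, both computed on non-missing calls), then
imputed chromosome-wise by a deterministic iterative k-nearest-neighbour
scheme (k = 5, Manhattan distance on shared markers of the chromosome, modal
vote, ties to the nearest neighbour, 3 sweeps), then pruned so that no
marker pair retains a squared correlation of exactly 1 (one member of each
perfect-LD clique survives, chosen with a seeded draw). Mask-and-recover
experiments on the generator put the imputation error around 9-11% at 5%
missingness -- adequate for the ~1,400-marker panels used here, though a
random-forest imputer fitted per chromosome would be expected to do somewhat
better on real data.

The genomic relationship matrix follows VanRaden: `K = W W' / (2 sum_k
p_k (1 - p_k))` with `W_ik = Z_ik + 1 - 2 p_k`. Allele frequencies default
to the data at hand but can be frozen from a training panel. Rows of K sum
to zero by construction, so K is singular -- everything downstream is built
to tolerate that.

A **haploblock** encodes a multi-allelic copy-number locus (the CBF cluster
at *Fr-A2* on chromosome 5A is the motivating case) through two flanking
SNPs: a line is +1 only when both components are homozygous for the
tolerance allele, -1 only when both carry the susceptibility allele, and 0
for every mixed or heterozygous combination. Published haploblock codings
address only the homozygous component cases; treating a heterozygous
component as block code 0 is this package's documented extension, as is the
explicit `favorable` allele orientation argument.

## Prediction models

With training BLUEs `y` and kinship `K` over training and candidate lines:

* **GS (GBLUP)**: `y = 1 mu + u_G + r`, `u_G ~ N(0, K sigma2_uG)`. The
  random vector spans *all* lines in K; candidates simply carry no
  observation, so their BLUPs are the kinship-propagated predictions. This
  joint mixed-model-equation formulation is exact and equivalent to the
  `K_vt K_tt^-1` projection.
* **wGS (weighted GBLUP)**: adds the haploblock codes as a fixed effect, the
  standard way of upweighting a known major locus. A haploblock that is
  monomorphic in the training set is an error, never a silent fallback to
  GS.
* **MAS (RR-BLUP)**: `y = 1 mu + Z_M u_M + r` with iid marker effects on a
  reduced marker set; candidate predictions are `mu + M u_M`. On identical
  marker sets and matched variance scaling this is algebraically the same
  model as GBLUP, and the tests assert the duality to 1e-6.
* **association scan**: per-marker fixed effect Wald test with the polygenic
  term `u_G ~ N(0, K sigma2_uG)`. Variance components are estimated once on
  the null model and reused across markers (the usual
  population-parameters-previously-determined shortcut); p-values use a t
  reference with n - 2 degrees of freedom. This is an approximation chosen
  so that the scan can run inside every cross-validation replicate;
  per-marker REML would be ~1,400 times more expensive and changes p-values
  negligibly at these sample sizes.

The **variance explained by a locus** is `rho_G = max(0, 1 -
sigma2G(locus fixed) / sigma2G(base))`, the relative drop in REML genetic
variance when the locus enters the fixed part -- the standard way of
quantifying how much of the genetic variance a fixed major locus absorbs.
Other estimators exist (e.g. regression-R2-based ones); this variance-ratio
definition is the package's documented choice.

## Marker pre-selection

Two routes reduce the panel for marker-assisted prediction, both driven by
the association scan and a forward stepwise regression that minimises the
OLS AIC on training BLUEs (the first marker is always taken; later additions
need strict improvement; ties in p-values break by larger absolute effect,
then map order, making the whole procedure a pure function of its inputs):

* **chromosome-wise**: per chromosome the 12 most significant markers enter
  a stepwise stage keeping 1-6; the pooled survivors (21-126 markers across
  21 chromosomes) are reduced by a second stepwise stage to at most 21;
* **genome-wide**: one stepwise stage over the 126 most significant markers.

The 12/6/126/21 constants are arguments, not constants in code. The
stage-2 reduction may stop below the cap when AIC stops improving. A seeded
uniform sample of markers provides the random baseline.

## The desired-gains index

Winter-hardiness and frost-tolerance predictions are combined as
`Index_i = X_WINT,i b_WINT + X_FROST,i b_FROST` with `b = G^-1 a`, where G
is the 2x2 covariance matrix of the predicted values across the candidate
lines and `a` the desired-gains vector, by default `diag(G)` ("one standard
deviation per trait"). G is estimated from the candidate (validation) line
predictions; using training predictions is available as an option.

One design point deserves emphasis. The two prediction vectors live on
incommensurate scales (a 1-9 score versus a percentage), so on raw scales
the larger-variance trait dominates `G` and the solve can assign the other
trait a *negative* weight, turning the index into a contrast and destroying
its accuracy -- we observed exactly this in replicated experiments.
`computeIndexWeights` therefore standardizes each prediction vector across
candidates before estimating G (`standardize = TRUE`, the default), which
keeps the desired-gains structure, makes the weights scale-free, and leaves
every textbook special case (diagonal G, zero gains on one trait)
unchanged. The raw-scale solve remains available. Perfectly correlated
predictions make G singular and raise an error advising a single-trait
model; both traits are treated lower-is-better, and a trait declared
`"higher"` is sign-flipped internally.

## Evaluation

Prediction accuracy is the Pearson correlation between predicted and
observed values on the shared lines, divided by the square root of the
heritability -- specifically the *validation* experiment's h2, since that is
the experiment whose noise attenuates the correlation; scaling by the
training h2 instead is a defensible alternative, and the choice is fixed and
documented here. The estimator can exceed 1 and is not clipped.

`crossValidate` repeats (100 times by default) a seeded disjoint split into
130 training and 30 validation lines, refits every model on the training
split only -- *including* the association scan and stepwise selection, which
are re-run inside each replicate, because selecting markers on the full data
leaks validation information and inflates MAS accuracy -- and summarises
mean, standard deviation and coefficient of variation per model.
`independentValidate` trains on resampled sets from two trait-specific
pools and evaluates against a third pool, adding the index of the two
single-trait predictions; when the validation pool equals the requested
validation size the same lines are used in every replicate.

## The synthetic-population generator

`simulatePopulation` emulates, with all defaults chosen once to match the
motivating breeding program:

* **504 inbred lines from 311 crosses** assigned round-robin to families;
  parents are mosaics of a 16-haplotype founder pool, and each line inherits
  one (doubled) parental haplotype per chromosome segment (3 segments per
  chromosome), with 2% residual heterozygosity. This produces elevated
  within-family kinship, founder-level linkage disequilibrium within
  chromosomes, and occasional perfect-LD marker pairs -- without a full
  coalescent model.
* **21 chromosomes x 67 SNPs** with founder allele frequencies drawn in
  [0.10, 0.50] and held inside those bounds at the founder-pool level;
  realized population frequencies drift through family sampling, which is
  realistic and exercised by the QC stage.
* **a multi-allelic major locus**: each founder haplotype carries 1-3
  copies (frequencies 0.3/0.4/0.3) of a copy-number allele whose effect
  pattern over 1/2/3 copies is (0, -1, -1.2) before scaling -- more copies
  confer tolerance, with diminishing returns. Two adjacent tag SNPs match
  the "2 or more copies" state with 95% per-haplotype concordance, so the
  observable two-SNP haploblock tags the causal state imperfectly, exactly
  the situation that motivates haploblock modelling.
* **an oligogenic background**: 60 QTL per trait at shared marker positions
  with correlated normal effects. An oligogenic rather than infinitesimal
  architecture is the deliberate choice: frost tolerance is reported to be
  influenced by loci on at least ten chromosomes, and a panel of ~20
  well-chosen markers can then retain most of the predictive signal, which
  is the regime the marker-pre-selection experiments probe.
* **exact calibration**: true breeding values are assembled from the
  centered major-locus effect vector and Gram-Schmidt-orthogonalised
  polygenic components, scaled so that in *every realized sample* the
  genetic variances equal `genetic_sd^2` (1.3^2 score-points^2 for winter,
  20^2 %^2 for frost), the genetic correlation equals
  `genetic_correlation` (default 0.6 -- a free parameter, not an estimate
  from the source data, which report no such correlation), and the major
  locus explains exactly `major_qtl_rho` (default 0.20) of the genetic
  variance. The tag-SNP concordance then degrades the *observable*
  haploblock R2 to ~0.15-0.18, inside the recovery band the tests assert.

Trial simulators add block (and optionally row/column) effects and residual
noise whose variance solves the configured entry-mean heritability under
the realized replication (`sigma2_e = r_eff * sigma2G (1 - h2)/h2`, with h2
floored at 0.01 so a zero-heritability configuration stays finite). Winter
scores are rounded and clipped to 1-9 -- the rounding noise (~1/12) is
discounted from the residual variance -- and frost damage is truncated at 0
and 100. Defaults: field trials with two blocks and partial replication
(replicated entries appear in both blocks), frost experiments as randomized
complete blocks with four replicates, h2 0.71 (winter) and 0.98 (frost).

**What the generator does not contain**: vernalization or photoperiod
physiology, weather, epistasis, genotype-by-environment interaction beyond
independent trial noise, and any environment-specific re-ranking of the
winter-hardiness trait. Passing tests therefore demonstrate the *methods*
behave correctly under a realistic but idealised genetic architecture; they
are not evidence about any particular real population. In the
independent-validation experiments, the genetic distance between training
and validation subpopulations is emulated by drawing the winter-hardiness
training pool from a disjoint block of early-cycle families.

## Problem sizes used by the tests and the acceptance script

Module tests run on reduced instances (typically 120-160 lines, 200-420
markers) chosen so each oracle comparison is sharp; parameter-recovery
checks use the study-like sizes that matter for the quantity in question
(180 lines for field h2, 213 lines x 4 blocks for chamber h2 and rho_G,
averaged over 30 generator seeds). The replicated evaluation experiments use
100 cross-validation replicates at 130/30 and 130/90 splits on 160- and
400-line populations with ~420 markers; the acceptance script runs the full
504-line, ~1,400-marker configuration once end to end. These sizes are the
package's own balance between Monte-Carlo sharpness and a desk-scale run.

## Known limitations

* Spatial analysis is limited to random row/column effects; autoregressive
  residual structures are out of scope.
* The kNN imputer is deterministic and local; it does not model
  marker-marker interactions across chromosomes.
* No multi-trait REML: the index operates on single-trait predictions
  rather than on a joint two-trait fit.
* No Bayesian whole-genome regressions, dominance, or epistasis.
* The accuracy estimator divides by the validation h2; when that h2 is
  itself estimated with error, accuracies inherit that noise.
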