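---
title: "Cross-cohort NPX analysis: models, assumptions and design choices"
author: "npxcc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort NPX analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npxcc)
```

## The problem

Targeted affinity proteomics panels (proximity extension assays reporting
NPX, a relative abundance unit on the log2 scale) are run plate by plate.
When two cohorts are measured on separate plate sets, every protein acquires
a cohort-level technical offset that is indistinguishable, within the data
matrix itself, from biology. The standard remedy is *bridging*: aliquots of
one pooled plasma sample are measured on every plate of both cohorts, and
the per-protein difference of the pooled-control medians estimates the
technical offset.

`npxcc` implements that pre-analytical chain and the downstream analyses a
two-cohort inflammation-panel comparison needs: covariate-adjusted
differential expression with empirical-Bayes variance moderation,
host-factor and SNP association scans, two-layer unsupervised clustering of
a food-derived metabolome and the proteome, and a metabolite-by-protein
regression matrix. A synthetic-cohort generator with a full ground-truth
record makes every stage testable without access to restricted cohort data.

## Bridging normalization

For each protein $p$ the offset is
$X_p = \mathrm{median}(\text{bridge NPX}_{A,p}) -
\mathrm{median}(\text{bridge NPX}_{B,p})$,
computed from the eight pooled controls per cohort (two per plate, four
plates). $X_p$ is subtracted from every cohort-A value of protein $p$ —
study and bridge samples alike — and from cohort A's limit of detection, so
below-LOD status is invariant under bridging. The median uses the midpoint
convention for even counts, which matters at $n = 8$. After bridging, the
two cohorts' bridge medians agree to machine precision by construction.

Two properties worth keeping in mind:

* **Translation equivariance.** Adding a constant to all cohort-A values
  changes $X_p$ by the same constant and leaves the bridged matrix
  unchanged, so bridging removes any cohort-wide technical shift exactly.
* **Variance propagation (a real limitation).** $X_p$ is estimated from
  8 + 8 pooled controls, so subtracting it injects the sampling noise of two
  8-sample medians (standard error $\approx 0.44\,\tau$ each, with $\tau$
  the technical replication noise of the controls) into every subsequent
  cross-cohort contrast. Downstream tests treat the bridged values as fixed
  and therefore understate cross-cohort uncertainty slightly. This is
  inherent to bridging with a handful of controls, not an implementation
  artifact; it is why the package's null-calibration checks of the testing
  engine are run on cohort pairs that need no bridging.

## Quality control

* **Below-LOD rule.** Values below the limit of detection are *retained as
  measured* — never imputed — and only counted. A protein is excluded when
  its below-LOD fraction strictly exceeds 25% of study samples; a value
  exactly at the LOD counts as detected. Three family variants are
  implemented: `both` (excluded only when over threshold in both cohorts),
  `either`, and `per_cohort` (independent per-cohort exclusion, the
  default). The default is `per_cohort` because the two rules genuinely
  differ in what they retain and the per-cohort variant reproduces
  cohort-specific retained panels; cross-cohort analyses then work on the
  intersection of the retained sets.
* **Outlier rule.** Principal-component scores (singular value
  decomposition of the centered, unit-variance-scaled study matrix, with
  each component's sign fixed so its largest-magnitude loading is positive)
  are screened on PC1 and PC2; a sample further than 3 standard deviations
  from a component mean on either component is excluded. The rule is
  applied once, per cohort, with no re-iteration — so its null flag rate on
  Gaussian data is $2 \times 2\,\Phi(-3) \approx 0.54\%$, and it is *not*
  idempotent: rerunning it on its own output re-flags fresh samples at that
  tail rate. Screening is per cohort by default because exclusion decisions
  are cohort-level; a combined-matrix mode is available.
* **Stage order** is fixed: bridge, then LOD filter, then outlier removal.
  Bridging first keeps the LOD comparison on a common scale; outlier
  screening last keeps it on the retained panel.

## Differential expression

Per protein, ordinary least squares of NPX on a cohort indicator (cohort A
coded 1) plus covariates (age, sex reference-coded with male as reference,
BMI continuous). The cohort coefficient is reported as the log2 fold
change. Residual variances are shrunk toward a panel-wide prior by
empirical Bayes: modelling $s_g^2 \sim s_0^2 \chi^2_{d_0}/d_0$ (scaled
inverse chi-square across proteins), the posterior variance is

$$ s^2_{\text{post},g} = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, $$

and the moderated $t$ uses $d_0 + d_g$ degrees of freedom. The prior
$(d_0, s_0^2)$ is estimated by moment matching on the log residual
variances: the excess of their variance over the sampling component
$\psi_1(d_g/2)$ identifies $d_0$ through a Newton inversion of the trigamma
function, and the mean identifies $s_0^2$. When the observed spread does
not exceed the sampling expectation, $d_0 = \infty$ and the prior is the
df-weighted pooled variance. The engine is written in the package and
cross-checked in the test suite against limma, which implements the same
model; $d_0 = 0$ reproduces classical OLS inference to $10^{-10}$ relative
error, and $d_0 = \infty$ uses the common prior for every protein.
Multiplicity is controlled by Benjamini–Hochberg step-up FDR within the
contrast (one family per analysis; the package does not pool families
across analyses). The significance gate is FDR < 0.05; the |log2 FC| > 0.5
line is a display annotation, not a gate. Moderation can be disabled
(`moderated = FALSE`) since the upstream analysis framework does not pin
down which variant was used; moderated is the default.

The paired pre/post contrast (dietary-intervention design) is the mean
within-subject difference, post minus pre, with the paired $t$-test —
negative coefficients are reductions after the switch.

## Association scans

* **Host factors** (age, sex, BMI, season, residency, categorical
  exposures): per analyte, OLS of the analyte on the factor plus
  covariates; by default the covariates are the other two of
  {age, sex, BMI}, mirroring the "correct for the others to isolate one
  factor" pattern. BH FDR is applied across analytes within one
  (factor, cohort) scan, with stars at FDR < 0.05 (*), < 0.005 (**),
  < 0.0001 (***), all strict. A standardized-coefficient option rescales
  the analyte (and a continuous factor) to unit variance.
* **pQTL scan**: per (SNP, protein) pair, an additive-dosage linear model
  with age and sex as covariates (the exact covariate set upstream is
  unstated; age + sex is the documented assumption). P-values are left
  unadjusted and pairs are flagged at the conventional genome-wide
  ($5\times10^{-8}$) and suggestive ($5\times10^{-6}$) thresholds.
  Monomorphic SNPs are skipped.

## Two-layer clustering

The food-derived metabolome (the `food_derived` flag is consumed as input;
ontology curation is upstream) is clustered first: Ward linkage on
Euclidean distances of the z-scored log intensities, tree cut at $k = 2$ —
deterministic, no seed. The proteome is clustered by k-means on z-scored
NPX with 100 random restarts, keeping the lowest within-cluster sum of
squares; the seed is recorded and the same seed reproduces the assignment
bit for bit. Features are standardized before distances in both layers
because the panels mix proteins with very different dynamic ranges
("relative expression" clustering). Labels are canonical — metabolome:
cluster 1 is the larger cluster; proteome: cluster 1 is the lower-expressed
cluster by mean NPX — so repeated runs compare equal. The upstream
description of the proteome clustering is internally inconsistent
(hierarchical in one place, k-means in another); both are implemented, with
k-means as the proteome default and Ward as the metabolome default.

Cluster–annotation enrichment uses the Pearson chi-square test
(uncorrected; Fisher's exact when any expected cell is under 5) for
categorical annotations and the Mann–Whitney U test for continuous ones,
with the odds ratio (2×2) or rank-biserial correlation as effect size and
BH FDR across annotations.

## Metabolite–protein matrix

For every (food-derived metabolite, protein) pair:
`protein ~ metabolite + age + sex`, both protein and metabolite scaled to
unit standard deviation so the slope is a standardized beta. Computation
uses the Frisch–Waugh decomposition (covariates residualized out once; each
pair's OLS slope, SE and $t$ recovered exactly from residual
cross-products), which makes the 288 × 74 matrix essentially instant. FDR
is adjusted over the whole pair matrix by default — the most conservative
sensible family; a per-protein family is available by flag. The exported
table is complete; display curation (top-N) is left to the caller.

## The synthetic generator

`sim_config()` defaults encode the emulated study conditions: 318 + 416
study samples; 92 proteins; 4 plates per cohort with 2 pooled bridge
controls each; sparse cohort effects — 35 up-regulated proteins spanning
0.2–1.9 log2 and 20 down-regulated spanning −0.8 to −0.2, matching the
printed effect range of the comparison being emulated; age/sex/BMI
covariate effects on small protein subsets; per-protein cohort-A technical
offsets drawn from N(0, 0.5²); 18 proteins censored at the 0.35 LOD
quantile (and the rest at 0.02), so the >25% rule excludes exactly those
18; 1.6% of study samples turned into multivariate outliers; per-protein
noise variances drawn from a scaled inverse chi-square with $d_0 = 4$,
$s_0^2 = 0.25$ — the same family the moderation engine assumes, which makes
the prior-recovery check a fair test.

Choices where realism had to be decided once:

* **Bridge controls carry technical noise only** (`bridge_sd = 0.1` log2,
  roughly a 7% intra-assay CV): pooled aliquots have no biological
  variance, and assay validation data put replicate CVs in this range. This
  is what makes bridging informative at $n = 8$.
* **Residual plate offsets are small** (`plate_sd = 0.05`): the emulated
  exports are already inter-plate normalized upstream, so only residual
  plate structure remains.
* **Outliers are shifted 6 residual sds along one random sign direction
  shared within a cohort** (each sample on a random side of it), emulating
  a common-mode artifact such as hemolysis. A shared direction is what
  gives a two-component score rule a well-defined catch rate; mutually
  orthogonal per-sample directions would be provably invisible to PC1/PC2
  once there are more than two of them.
* **Metabolome**: 350 features of which 288 are food-derived; two latent
  diet clusters shift 120 food-derived features by 0.5 log2 against feature
  noise of 0.8; the diet cluster also shifts 30 proteins by 0.5 log2 (the
  diet-to-inflammation signal), and a handful of direct metabolite–protein
  couplings of ±0.3 standardized units mimic polyphenol–chemokine
  associations.
* **Genotypes**: six SNPs under Hardy–Weinberg equilibrium at minor allele
  frequencies 0.1–0.5, with no protein effects by default (the emulated
  scan found none).

What the generator does *not* emulate: skewed or heavy-tailed NPX noise,
LOD-censoring mechanisms correlated with biology, missing records,
linkage disequilibrium between SNPs, metabolome batch structure, and any
correlation structure among proteins beyond what the injected effects
induce. Passing tests therefore demonstrate correctness of the algorithms
under the stated generative model, not robustness to every failure mode of
real plasma panels.

## Numerical conventions

* Median: midpoint of central order statistics (`stats::median`).
* PCA: `prcomp` (SVD); sign fixed by the largest-magnitude loading;
  zero-variance features dropped before scaled PCA; missing cells mean
  filled with provenance recorded.
* Below-LOD: strict `<`; exactly-at-LOD is detected.
* LOD threshold: strict `>` 0.25 exclusion; exactly 25% is retained.
* k-means: `stats::kmeans`, `iter.max = 100`, best of `restarts`
  initializations under one recorded seed.
* Ties in canonical cluster relabelling: larger cluster first, then lower
  mean, then original label.
* Degenerate paired contrasts (all differences zero) report `p = NA` with
  a `degenerate` flag rather than a fabricated p-value.
* All simulation randomness flows from one master seed; per-stage seeds are
  derived from it by fixed offsets and recorded in the outputs.

## Problem sizes used in validation

The test suite and the acceptance script validate at the emulated study
scale — 318 + 416 samples and 92 proteins per simulated pair — using 200
replicate pairs for the null FDR calibration, 3 pairs (276 protein
estimates) for effect-recovery RMSE, 100 runs for the two-layer clustering
property, 40 × 700 samples for the outlier-rule calibration, and 500
proteins at 100 residual df for prior recovery. These sizes give the
relevant Monte-Carlo standard errors a comfortable margin relative to the
tolerances being checked.

## Known limitations

* Bridging variance propagation (above) is unaccounted for downstream.
* The moderated model assumes exchangeable protein variances; panels with
  variance strata (e.g. by dilution group) would want a stratified prior.
* Factor scans accept only binary or continuous factors; multi-level
  factors must be recoded into contrasts by the caller.
* The pQTL scan fits each pair independently; it is not a mixed-model or
  kinship-aware analysis and is meant for a handful of candidate loci.
* Below-LOD values are used as measured, which is the emulated study's
  choice; censored-likelihood alternatives are out of scope.
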