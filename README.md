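# npxcc — cross-cohort analysis of Olink NPX inflammatory proteomes

`npxcc` is an R package plus a numbered analysis workflow for comparing
targeted affinity proteomics panels (proximity extension assays reporting
NPX units on the log2 scale) between two cohorts measured on separate plate
sets — the setting of population comparisons of the circulating
inflammatory proteome, where cohort-level technical offsets must be removed
before any biology can be read off.

It is aimed at analysts working with Olink-style long-format NPX exports,
per-sample metadata, an untargeted plasma metabolome with food-derived
annotations, and (optionally) candidate SNP dosages.

## What it computes

1. **Bridging normalization.** Pooled plasma controls are measured on every
   plate of both cohorts (2 per plate × 4 plates = 8 per cohort). Per
   protein, the offset `X = median(bridge A) − median(bridge B)` is
   subtracted from every cohort-A value (and from its LOD, so below-LOD
   status is invariant). Post-bridge, the cohorts' bridge medians agree to
   machine precision.
2. **Quality control.** Proteins with a below-LOD fraction strictly above
   25% are excluded (per-cohort, both-cohort and either-cohort rules
   implemented); below-LOD values are kept as measured, never imputed.
   Samples beyond 3 standard deviations from the mean of PC1 or PC2 are
   excluded in a single pass.
3. **Differential expression.** Per protein,
   `NPX ~ cohort + age + sex + BMI`; the cohort coefficient is the log2
   fold change. Residual variances are shrunk by empirical Bayes
   (`s2_post = (d0·s0² + df·s²)/(d0 + df)`, moderated t with `d0 + df`
   degrees of freedom, prior estimated by moment matching on log
   variances), with Benjamini–Hochberg FDR and a 0.05 gate.
4. **Association scans.** Factor-by-protein regressions (age, sex, BMI,
   season, residency, exposures) with FDR stars, and a matrix pQTL scan
   (additive dosage models, unadjusted p, flags at 5e-8 / 5e-6).
5. **Two-layer clustering.** Ward/Euclidean clustering of the food-derived
   metabolome (k = 2), k-means (100 restarts, seeded) of the proteome, and
   chi-square / Mann-Whitney enrichment of annotations — including
   metabolome-cluster membership — across the proteome clusters.
6. **Metabolite–protein matrix.** Standardized betas of
   `protein ~ metabolite + age + sex` over all food-derived metabolite ×
   protein pairs, FDR over the whole matrix, chemical-class summaries.
7. **Synthetic cohorts.** `sim_config()` / `simulate_cohorts()` /
   `simulate_metabolome()` / `simulate_genotypes()` generate the full study
   design (318 + 416 samples, 92 proteins, plates, bridges, LOD censoring,
   covariate effects, outliers, diet clusters, couplings) with a complete
   ground-truth record, so every stage is testable offline.

## Worked example

The `analysis/` scripts run the whole study on a synthetic cohort pair and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_diffexp.R
Rscript analysis/04_scans.R
Rscript analysis/05_clusters.R
Rscript analysis/06_metabolite_links.R
```

Stage 2 prints the QC summary (seed 1):

```
<qc_report>
  proteins: 92 shared in; excluded A=18, B=18; retained A=74, B=74 (mode=per_cohort)
  samples: A 318 -> 313 (5 outliers), B 416 -> 408 (8 outliers)
bridge offsets: median 0.08 log2 (range -1.33..1.29), defined for 92/92 proteins
```

— the 18 heavily LOD-censored proteins are dropped, the planted outliers
are caught, and the per-protein bridge offsets (the technical shifts the
generator injected) are estimated and removed. Stage 3 then reports

```
<de_result> 74 proteins: 37 up, 20 down, 17 ns (FDR < 0.05)
log2 FC recovery vs injected truth: RMSE 0.086 over 74 proteins
moderation prior: d0 = 4.16, s0^2 = 0.258
```

— the 35 injected up- and 20 down-regulated effects are recovered (RMSE
0.086 log2 units; the generator's variance prior d0 = 4, s0² = 0.25 is
re-estimated from the residuals), and stage 5 finds the planted
diet-to-inflammation structure:

```
metabolome-cluster x proteome-cluster association: chi_square p = 1.39e-55 (OR 483.33)
```

Real data drops in at stage 2: point `read_npx_long()` at your own
long-format exports (columns `SampleID, Assay, Panel, NPX, LOD, PlateID,
QC_Warning, SampleType`) and `read_metadata()` at your metadata CSV.

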