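# coronaDx

Serum proteomics biomarker discovery from multi-nanoparticle protein-corona
enrichments, packaged as a tested, reusable pipeline.

## The problem

PSA blood testing flags many men for prostate biopsy who turn out not to have
cancer. A *PSA reflex test* — a follow-on blood test for men with moderately
elevated PSA (typically 4–10 ng/mL) — needs deeper serum proteome coverage
than conventional LC-MS workflows provide. Nanoparticle (NP) protein-corona
enrichment yields five intensity series per serum sample (one per NP
channel), spanning a wide dynamic range but with heavy left-censored
missingness and strong plate (batch) structure. `coronaDx` implements the
full discovery analysis for such data:

- **QC** (`computeCV`, `flagOutlierSamples`, `flagPeptideRecovery`): %CV of
  linear-scale MaxLFQ intensities per protein × NP × stratum,
  identification-count outliers, peptide-recovery flags against plate
  medians.
- **Study design** (`assignPlates`, `splitTrainValidation`): stratified
  plate randomization with Kruskal–Wallis/χ² balance checks and
  rerandomization, and a stratified 70/30 train/validation split.
- **Normalization** (`foldChangeNormalize`, `compositionCovariate`,
  `detectionFilter`, `imputeMNAR`): per-(sample, NP) median fold-change
  shifts estimated on high-coverage reference proteins, an "Extracellular"
  GO-CC sample-composition covariate, a 60%-missing detection filter, and
  left-censored imputation from `Normal(I0 − 1.8σ, 0.3σ)`.
- **Differential abundance** (`runDifferential`): per-protein linear mixed
  model, pooling NP channels,

  `y = β0 + β1·case + covariates + u(plate) + v(NP) + w(plate×NP) +
  z(subject) + ε`,

  fit by REML (lme4) with Wald-normal p-values and Benjamini–Hochberg
  correction; β1 is the case log2 fold change.
- **Enrichment** (`enrich1D`): rank-based 1D annotation enrichment — the
  rank-biserial score `s = 2U/(n1·n2) − 1 ∈ [−1, 1]` with Mann–Whitney
  p-values.
- **Classifier** (`nestedCV` and friends): Wilcoxon feature ranking,
  coverage-aware correlation filtering, random forest with inner-CV `mtry`
  tuning, evaluated by AUC, average PPV (area under precision–recall) and
  average NPV (area under NPV–specificity), in nested cross-validation over
  a grid of (m, ρ) configurations.
- **BBC-CV** (`bbcEvaluate`, `holdoutValidate`, `summarizeImportance`):
  bootstrapped bias-corrected cross-validation — select the best
  configuration on in-bag subjects, score it and a clinical benchmark on
  out-of-bag subjects — plus held-out validation tests (paired DeLong for
  AUC) and selection-frequency-weighted permutation importance.
- **MaxID** (`maxidSelect`, `saturationCurve`): greedy maximum-coverage
  sample selection for spectral-library building.
- **Synthetic cohorts** (`simulateCohort`): a generator with ground truth —
  wide dynamic range, per-protein plate/NP/subject variance components,
  extracellular composition shifts, detection-limit (MNAR) censoring,
  planted differential proteins, and a benchmark score with tunable AUC —
  so every stage is testable without any data download.

## Worked example

```r
library(coronaDx)

sim <- simulateCohort(simParams(n_subjects = 90, n_proteins = 120, seed = 7))
q <- sim$quant
q
#> NPQuant: 120 protein groups x 90 samples, 5 nanoparticle channels ( NP1, NP2, NP3, NP4, NP5 )
#>   missingness per NP: NP1=17.2% NP2=19.4% NP3=17.8% NP4=18.8% NP5=18.2%

qn <- foldChangeNormalize(q)
de <- runDifferential(qn, sim$annotations, seed = 11)
cat("proteins eligible:", nrow(de), "| significant at q < 0.05:",
    sum(de$q < 0.05, na.rm = TRUE), "\n")
#> proteins eligible: 108 | significant at q < 0.05: 12

head(de[order(de$q), c("protein_group", "beta", "se", "p", "q")], 5)
#>     protein_group       beta         se             p             q
#> 68         PG0075  2.4542371 0.07394282 1.451218e-241 1.567316e-239
#> 58         PG0065 -1.3370527 0.06709505  2.338925e-88  1.263020e-86
#> 103        PG0114  1.4408359 0.07713795  7.380944e-78  2.657140e-76
#> 42         PG0048  0.7572902 0.06124013  3.996331e-35  1.079009e-33
#> 5          PG0007 -0.8096151 0.07171603  1.484153e-29  3.205772e-28
```

Twelve protein groups pass FDR < 0.05; this cohort planted 12 true
differential proteins, and the top hits' `beta` values (case-vs-control
log2 fold changes) recover the planted effects. Downstream,
`nestedCV()` + `bbcEvaluate()` estimate how well a multimarker signature
built from these features would classify new subjects, and compare it
against the per-sample clinical benchmark score in `sampleMeta(q)`.

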