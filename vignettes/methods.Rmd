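---
title: "Methods: models, parameters and design choices in coronaDx"
author: "coronaDx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in coronaDx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coronaDx` analyses serum proteomes measured through five nanoparticle (NP)
protein-corona enrichments per sample. This vignette is the package's own
account of the statistics it implements: the models and their assumptions,
the tunable parameters, what the synthetic cohort generator does and does
not emulate, the numerical conventions, and the limitations we know about.

## 1. Data model

The central container, `NPQuant`, extends `SummarizedExperiment`: one assay
per NP channel, rows are protein groups, columns are samples, entries are
log2 MaxLFQ intensities, and `NA` marks observations that were not
quantified. Explicit nulls and absent records are canonicalized to `NA` on
ingest, so "missing" has a single representation. Sample covariates (case
status, Gleason grade group, PSA in ng/mL, age in years, draw year, plate,
appearance flag, benchmark risk score in [0, 1]) live in `colData`.

## 2. Fold-change normalization and the frozen reference profile

For each NP channel, a protein's fold change in a sample is its log2
intensity minus that protein's cohort median. The shift of a (sample, NP)
run is the median fold change over the *reference set* — proteins detected
in at least 80% of samples (boundary inclusive) — and every intensity of
the run is normalized by subtracting its shift. Runs with no observed
reference protein get shift 0, and an empty reference set falls back to
all proteins (both with a warning or logged decision).

A design point worth making explicit: the per-protein cohort medians and
the reference set are estimated **once** and then frozen in the object
metadata. Renormalizing an already-normalized object, or applying a
training-cohort profile to held-out samples, computes shifts against the
frozen profile, so a sample's shift depends only on its own intensities.
Two consequences follow *exactly* (to floating-point precision, and the
test suite asserts them at 1e-9):

- **Idempotence** — renormalizing is a no-op;
- **Location equivariance** — adding a constant to one sample raises that
  sample's shift by the same constant and leaves its normalized values and
  every other sample untouched.

If instead the median profile is re-estimated after a perturbation
(`refit = TRUE`), both properties hold only approximately: moving one
sample re-orders per-protein order statistics, and deviations on the scale
of the inter-sample gaps (~0.1 log2 units on small cohorts) appear. No
location estimator computed from the data avoids this, which is why the
frozen-reference semantics is the default. The classifier requires the
same fit/apply split anyway to keep cross-validation leakage-free.

## 3. Sample composition covariate

Variation in how much extracellular blood-subfraction material each serum
sample contributes to the NP corona acts as a sample-level confounder. We
quantify it as the per-sample median fold change, on the **normalized**
table, over all observed (protein, NP) pairs annotated to the
"Extracellular" GO Cellular Component. Computing it on raw data would
confound it with the very shifts normalization removes; on normalized data
the estimator tracks the simulated ground truth closely (the acceptance
script reports the recovery correlation). Samples with no annotated
observation get `NA` and are mean-imputed downstream. The covariate pools
NP channels within a sample: the downstream models consume one value per
sample.

## 4. Detection filtering and left-censored imputation

Protein–NP series missing in **60% or more** of samples are excluded from
differential analysis (boundary exclusive for the classifier's feature
filter, which drops only series *more than* 60% missing — the two stages
state their rules differently and both are implemented as stated). For
each remaining protein, only the NP channel with the most non-missing
values is imputed; other channels contribute observed values only.

Imputation assumes missingness is left-censoring at the instrument
detection limit: missing entries are drawn independently from
`Normal(I0 − 1.8·σ, 0.3·σ)`, where `I0` and `σ` are the mean and standard
deviation of all non-missing log2 intensities in the dataset (a per-sample
variant exists behind `per_sample = TRUE` for sensitivity analysis). The
downshift (1.8) and width (0.3) are the field's standard convention for
this family of imputers. Draws are seeded per protein through a hash of
the protein id and assigned in sample-name order, so results are invariant
to row and column ordering of the input.

## 5. Per-protein linear mixed model

For protein intensities `y` pooled across NP channels, with plate `i`,
NP `j`, subject `k`:

```
y = b0 + b1*case + b2*age + b3*draw_year + b4*appearance + b5*composition
    + u_i + v_j + w_ij + z_ik + e
```

with independent Gaussian random intercepts for plate, NP, plate×NP, and
subject nested in plate, fit by REML with lme4. `b1` is the case-status
log2 fold change. Proteins quantified in a single NP drop `v`, `w`, `z`
and keep the plate intercept. Fixed covariates that are constant in a
cohort are dropped from the formula. Fits that fail are retried on a
reduced random-effect chain (drop plate×NP, then NP, then everything but
plate); a protein whose fits all fail is reported with `converged = FALSE`
and excluded from the Benjamini–Hochberg family.

**p-values are Wald-normal** on the REML fit: `p = 2·Φ(−|b1/se|)`. lme4
deliberately reports no denominator degrees of freedom; with ~200 subjects
the normal reference is adequate, and the choice is recorded in the result
attribute `p_method`. Satterthwaite-type corrections are out of scope.

The three-level contrast (no cancer / GG 1 / GG ≥ 2, reference no cancer)
reports the GG ≥ 2 coefficient as `beta` and the GG 1 coefficient in
`beta_gg1`.

## 6. Enrichment

1D annotation enrichment scores a term by comparing member versus
non-member values (mixed-model betas; by default only proteins significant
at q < 0.05, with `significant_only = FALSE` to score all) with a
two-sided Mann–Whitney test. The reported score is the rank-biserial form
`s = 2U/(n1·n2) − 1`, which lies in [−1, 1] and is positive when members
rank high. Midranks handle ties; the p-value is exact when `n1·n2 ≤ 400`
and tie-free, otherwise normal with tie correction; a term whose values
are all tied gets `s = 0, p = 1`; terms with fewer than 3 scored members
are skipped.

## 7. Classifier pipeline

Features are (protein, NP) pairs. On each training cohort: drop features
more than 60% missing; fold-change normalize against training medians;
estimate the composition covariate; residualize each feature against
`y ~ composition + (1 | plate)`; zero-impute what remains missing
(assuming absent-in-sample); record per-feature training coverage.
Held-out samples are transformed with the frozen training models — unseen
plates contribute no random-intercept term.

Ranking uses two-sided Wilcoxon rank-sum p-values (normal approximation
with tie correction), ties broken by |rank-biserial| then feature name.
The correlation filter works on the top-1000 pool: feature F is excluded
when any pool feature with signed Pearson correlation above the cutoff ρ
has strictly higher coverage than F; comparisons run against the whole
pool, not only retained survivors, following the rule's "iterates through
all features" reading. An absolute-correlation mode is available behind a
flag. The top m survivors feed a 500-tree random forest (ranger),
probability machine, with `mtry` tuned over `{√d/2, √d, 2√d}` by inner-CV
AUC. The evaluation grid crosses m ∈ {20, 40, 50, 80, 100, 125, 160, 200}
with ρ ∈ {0.5, 0.6, 0.7, 0.8}; nested cross-validation uses 10 outer and
10 inner folds, repeated over 3 seeds, with every selection stage refit
inside each outer-training split. Metrics are the Mann–Whitney AUC,
average PPV (step-integrated area under precision–recall) and average NPV
(the same computation on reversed scores and labels). Configuration
selection maximizes the summed z-scores of the three metrics across
configurations (zero-variance metrics contribute 0; ties break to smaller
m, then smaller ρ). A PSA window (e.g. 4–10 ng/mL) can restrict subjects
before splitting.

## 8. BBC-CV, held-out validation, importance

Out-of-fold scores are averaged per subject over the repeat seeds (the
alternative — treating repeats as separate rows — is available via direct
matrix input). Each of B = 500 bootstrap iterations resamples subjects
with replacement, selects the best configuration on in-bag rows by the
composite criterion, and evaluates it and the clinical benchmark on the
identical out-of-bag rows; single-class draws are redrawn so B stays
fixed. Point estimates are means over iterations with 2.5/97.5 percentile
intervals. Held-out validation tests are one-sided: paired DeLong for the
AUC difference, paired bootstrap mid-p for average PPV/NPV (so identical
score vectors give p = 0.5 and swapping the roles of the two scores maps p
to 1 − p). Feature importance is ranger's scaled permutation importance,
averaged over (seed, fold) fits of a configuration with absent features
counting 0, then weighted by the configuration's BBC selection frequency.

## 9. MaxID

Greedy maximum coverage over a boolean sample × peptide matrix: each step
adds the sample covering the most new peptides; ties break to the
lexicographically smallest sample id; stopping at k samples, at a coverage
target, or at zero gain. Greedy gains are non-increasing (coverage is
submodular) and the classical (1 − 1/e) optimality bound applies; the test
suite verifies it against exhaustive optima on 8-sample matrices.

## 10. The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the analysis
assumes, with ground truth for every planted quantity:

- protein base abundances uniform over a 10 log2-unit range (a wide serum
  dynamic range);
- **per-protein** variance components: plate (sd 0.2), NP (0.3),
  plate×NP (0.1), and subject (0.3, shared across a subject's channels) —
  drawn per protein because the downstream model is fit per protein and
  its random effects are protein-specific quantities; a sample-level
  rendering of these effects would be removed wholesale by normalization
  and leave the variance components with nothing to estimate;
- residual noise sd 0.3 log2 units;
- 10% planted differential proteins; |log2FC| ~ Gamma(shape 4) with mean
  `effect_size_log2` (default 1.0) and random signs;
- a per-sample composition scalar (sd 0.5) loading only on the 25% of
  proteins annotated "Extracellular", with protein loadings U(0.5, 1.5);
- detection-limit censoring: missingness probability
  `plogis(−6 − 2·(y − grand mean))`, i.e. a steep logistic centred two
  global sd below the grand mean. This encodes the same assumption the
  imputation model makes — values go missing because they fall below an
  instrument detection limit — and gives ~20% overall missingness,
  concentrated in low-abundance proteins. `missing_slope = 0` provides an
  MCAR switch for null experiments;
- plates of 15 filled round-robin from shuffled case and control streams
  (controls in reverse plate order so no plate overflows);
- PSA log-normal clipped to [0.1, 50] ng/mL so a 4–10 window has
  non-trivial membership; age ~ N(64, 7); draw years 2000–2016;
- a binormal benchmark score with target AUC 0.70 (cases shifted by
  `√2·Φ⁻¹(AUC)`), mapped monotonically to [0, 1].

The same seed yields byte-identical cohorts; all randomness flows through
seeded local RNG streams that restore the caller's RNG state.

**What it does not emulate:** peptide-level quantification, retention-time
or ion-mobility structure, instrument drift, correlated protein modules
(beyond the extracellular block), cohort-specific storage effects, or any
real biology of prostate cancer. A green test on synthetic data shows the
*procedures* behave as specified under the assumed generative model — not
that the markers found in any real cohort are correct.

## 11. Known limitations, measured honestly

Two distortions inherent to this class of pipeline are visible at desk scale, and
we report rather than hide them (the acceptance script computes all the
quantities involved):

1. **MNAR truncation attenuates effects.** Only the best-covered NP
   channel is imputed; the other channels enter as observed-only series.
   Under left-censoring their low tails are truncated, which pulls case
   and control means toward each other for proteins near the detection
   limit. Planted log2 fold changes are attenuated by several percent on
   average — far more for high-missingness proteins — and nominal 95%
   confidence intervals under-cover there (the acceptance suite's coverage
   check is expected to fail its [0.92, 0.97] band for exactly this
   reason, while the bias and null type-I checks pass).
2. **Planted signal leaks into cohort-level estimators.** The reference
   median shifts and the composition covariate are computed from the data;
   with 10% of proteins differential, case samples' shifts absorb a small
   case-status offset that propagates to every protein. Inside a planted
   cohort the null-protein type-I error and the empirical FDR inflate
   relative to a fully null cohort (where calibration is clean). The
   effect scales with the planted fraction and is an order of magnitude
   smaller at the few-percent significant fractions seen in real serum
   cohorts.

Other limitations: Wald-normal p-values (no small-sample df correction);
single imputation (no propagation of imputation uncertainty); the
composite selection criterion weights the three metrics equally; AutoML
alternatives are a plug-in classifier interface only, not re-implemented.

## 12. Problem sizes used by the test and acceptance runs

Test and acceptance runs size their simulations for single-CPU desk-scale
execution: calibration cohorts of 200 subjects × 300 proteins (500 for the
null type-I check), nested CV at 200 subjects × 30 proteins on a reduced
2 × 2 grid with 5 outer / 4 inner folds and 150 trees, BBC with B = 500,
and MaxID brute-force comparisons on 8 × 30 matrices where exhaustive
optima are enumerable. Full-scale defaults (the 8 × 4 grid, 10 × 10 folds,
3 seeds, 500 trees) remain the exported function defaults.
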