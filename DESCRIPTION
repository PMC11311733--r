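Package: coronaDx
Title: Serum Nanoparticle Protein-Corona Biomarker Discovery Pipeline
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for serum proteomics biomarker discovery from
    multi-nanoparticle protein-corona enrichments: quality control of MaxLFQ
    protein-group intensities, fold-change normalization with an extracellular
    sample-composition covariate, left-censored (MNAR) imputation, per-protein
    linear mixed-model differential abundance with crossed plate and
    nanoparticle random effects, rank-based 1D annotation enrichment, a
    feature-filtered random-forest classifier evaluated by nested
    cross-validation, bootstrapped bias-corrected cross-validation (BBC-CV)
    against a clinical benchmark score, greedy maximum-coverage sample
    selection for spectral-library building, and a synthetic cohort generator
    with ground truth so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    ranger,
    pROC
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, DifferentialExpression, Classification
RoxygenNote: 7.3.3
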