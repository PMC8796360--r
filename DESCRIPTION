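Package: sspRules
Title: Single-Sample Multiclass Transcriptomic Predictors Based on Gene-Pair Rules
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training, prediction and evaluation for single-sample multiclass
    transcriptomic classifiers. Implements nearest-centroid predictors built on
    raw or centered expression values, one-versus-rest multiclass k-Top-Scoring-Pairs,
    a Naive-Bayes-over-rules classifier with cross-validated rule-count selection,
    and a three-stage rule-based Random Forest pipeline with gene and rule
    importance selection, shadow-feature pruning, out-of-bag scoring, proximity
    extraction and k-nearest-neighbour rule imputation for missing genes.
    Includes a synthetic multi-platform, variable-purity cohort simulator with
    recorded ground truth, and a shared evaluation harness (accuracy, tied scores,
    score margins, per-rule platform-specificity diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'centroid.R'
    'core_data.R'
    'evaluation.R'
    'pair_rules.R'
    'ktsp.R'
    'model_utils.R'
    'nb_rules.R'
    'rf_rules.R'
    'sspRules-package.R'
    'synthetic.R'
    'utils.R'
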