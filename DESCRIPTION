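Package: metabomark
Title: Predictive Metabolomics: Chemotype and Maternal-Genotype Markers from
    Untargeted Feature Tables
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predictive metabolomics on untargeted LC-MS/GC-MS
    feature tables: blank-ratio and presence filtering, internal-standard,
    dry-weight and median normalisation, cube-root transformation and Pareto
    scaling; per-feature ANOVA with Tukey HSD and Benjamini-Hochberg FDR;
    a resampled multinomial elastic-net ensemble with stratified
    train/validation/test splits, occurrence-based marker selection,
    permutation-null validation and cross-batch model transfer; and variation
    partitioning of chemical variance between chemotype and maternal genotype
    via partial redundancy analysis. Includes a synthetic-data generator with
    a planted ground-truth ledger so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0),
    S4Vectors,
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'preprocess.R'
    'ensemble.R'
    'univariate.R'
    'varpart.R'
    'io.R'
    'metabomark-package.R'
    'synthetic.R'
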