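Package: ovca
Title: Molecular Subtyping and Functional Screen Analysis for Epithelial
    Ovarian Cancer
Version: 0.1.0
Authors@R:
    person("OVCA", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for discovering molecular subtypes of
    epithelial ovarian cancer from log-scale expression data and for
    identifying subtype-specific growth-essential genes from pooled shRNA
    screens. Provides empirical-Bayes batch adjustment, resampled consensus
    clustering with silhouette and Gaussian-null cluster significance
    validation, single-sample gene set enrichment scoring with SAM/ROC set
    selection, Bayesian probit metagene subtype predictors with
    cross-validation, ranked-hairpin screen enrichment (weighted
    Kolmogorov-Smirnov with a permutation null and Benjamini-Hochberg FDR),
    survival statistics (Kaplan-Meier, log-rank, Cox proportional hazards),
    GI50 dose-response estimation, and a synthetic-data module that emulates
    multi-batch cohorts, gene sets, survival outcomes and pooled screens so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
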