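Package: gaitPLSDA
Title: PLS-DA Profiling of Circulating Inflammatory Biomarkers by Gait-Speed Category
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Partial least squares discriminant analysis (PLS-DA) of
    multiplex inflammatory-biomarker panels in two-group cohort designs,
    such as older adults dichotomised into normal and slow walkers at the
    0.8 m/s gait-speed cutoff. Implements a NIPALS PLS1 engine, dummy-coded
    two-class discrimination with a 0.5 decision threshold, variable
    importance in projection (VIP) marker selection, double (nested)
    cross-validation for honest complexity selection and error estimation,
    and permutation tests building empirical null distributions of the
    number of misclassifications (NMC), AUROC, and discriminant Q2 (DQ2).
    A synthetic-cohort generator with lognormal moment matching and an
    optional Gaussian copula emulates the statistical structure of
    multiplex cytokine panels so the whole pipeline is testable without
    individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Classification, StatisticalMethod, ImmunoOncology, Proteomics
RoxygenNote: 7.3.3
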