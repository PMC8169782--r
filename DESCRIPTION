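Package: lipidScreen
Title: Untargeted Lipidomics Biomarker Discovery with OPLS-DA and
    Diagnostic Panels
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end biomarker discovery for untargeted lipidomics
    cohort studies. Builds a theoretical lipid mass database (sum
    compositions with ESI adducts), annotates observed peaks by exact
    mass within a ppm window with optional MS/MS confirmation of
    class-diagnostic fragments, screens features by Mann-Whitney
    U-tests, fits OPLS-DA models with cross-validated Q2 and VIP-based
    marker selection, evaluates logistic-regression diagnostic panels
    by leave-one-out cross-validation, and performs hypergeometric
    lipid-class enrichment. A synthetic cohort generator with planted
    fold changes provides ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Lipidomics, MassSpectrometry, Classification, Software
RoxygenNote: 7.3.3
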