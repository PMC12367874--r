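Package: cardiotoxsig
Title: Discovery of Metabolic Signatures of Structural Cardiotoxicity from
    Untargeted Metabolomics Peak Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid-metabolomics analysis pipeline for in vitro cardiotoxicity
    studies on cardiac microtissues. Provides weighted calibration-curve
    quantitation of free xenobiotic concentrations with bioanalytical acceptance
    rules, discovery of xenobiotic biotransformation products by mass-shift rule
    enumeration, peak-matrix quality filtering with QC-based robust spline drift
    correction, endogenous feature grouping and putative compound annotation,
    condition-wise Welch scans against matched controls, and an OPLS-DA
    implementation with VIP-based feature refinement, permutation validation,
    cross-validation and ROC analysis, used to mine intracellular and
    extracellular peak matrices for a multivariate signature predictive of
    structural cardiotoxicity. Includes a synthetic-study generator that
    emulates the multi-batch exposure design, injection-order drift, batch
    effects, heteroscedastic noise, intensity-dependent missingness and planted
    ground-truth features, so that the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
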