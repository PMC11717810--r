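Package: goblup
Title: Genomic and Multi-Omics BLUP for Plant Breeding Field Trials
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Variance-component estimation and breeding-value prediction for
    replicated plant breeding field trials using genomic (GBLUP) and joint
    genomic-plus-omics (GOBLUP) linear mixed models. Implements SNP quality
    control and mean-dosage imputation, the VanRaden genomic relationship
    matrix, a neighbour-based spatial similarity kernel, metabolomic and
    near-infrared similarity kernels (with Savitzky-Golay derivative
    preprocessing and PCA compression), dense AI-REML with EM fallback,
    Henderson mixed-model BLUP, the two-step GOBLUP procedure with combined
    breeding values, plot-level heritability decomposition
    (h2 = h2_d + c_m2 * h2_M), a simulation-based significance test for
    feature heritabilities, fivefold and leave-one-breeding-cycle-out
    cross-validation with LR-method accuracy ratios, bootstrap standard
    errors and paired model comparisons, and a synthetic breeding-trial
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
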