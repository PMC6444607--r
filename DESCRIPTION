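Package: autalasso
Title: Automatic Adaptive LASSO for Genome-Wide Prediction via ADMM
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sparse whole-genome regression for genomic prediction and
    marker-effect estimation. Fits the (weighted) adaptive LASSO by the
    alternating direction method of multipliers (ADMM) with proximal
    updates, tunes the learning rate automatically by Armijo backtracking
    line search and the regularization factor by golden-section search on
    held-out squared test error. Includes genotype one-hot encoding with
    minor-allele-frequency filtering, extraction of additive and dominance
    SNP effects from genotype-class coefficients, a synthetic QTL-trait
    simulator with additive, dominance, over-dominance and under-dominance
    loci for end-to-end testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
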