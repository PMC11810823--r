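Package: rtblup
Title: Linear Mixed Model Comparison for Feather Score Genetic Evaluation
    in Recurrent Testing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and genetic evaluation of feather score and survival
    records from recurrent progeny tests of laying hens, where paternal
    half-sib daughters are housed together in cages. Provides a
    liability-threshold generator for the half-sib cage design, pedigree
    relationship matrices and their sparse inverses, a sparse REML/BLUP
    engine for univariate and bivariate sire and animal models at the
    individual or cage level, and a cage-masked 10-fold cross-validation
    framework measuring accuracy, dispersion and total heritable variance
    of estimated sire effects, with estimated-marginal-mean model
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    emmeans
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
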