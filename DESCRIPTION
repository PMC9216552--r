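Package: logicpath
Title: Perturbation Effect Prediction on Pathway-Derived Logical Networks
Version: 0.1.0
Authors@R:
    person("logicpath", "developers", email = "logicpath@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the downstream effects of perturbing root
    inputs of curated biological pathways represented as Logical Networks:
    signed directed graphs whose nodes combine their inputs under AND or OR
    logic. Provides readers and writers for logic-table TSV files, seeded
    generators of synthetic networks with brute-force ground truth, an
    automated implementation of the curators' path-parity prediction rules,
    a continuous-activity optimization model that propagates fold-change
    perturbations through the logic equations, cutoff calibration of the
    continuous output against reference three-class calls, and a
    direction-aware evaluation framework (confusion matrices with
    wrong-direction false positives, Cohen's and Fleiss' kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
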