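Package: netcox
Title: Network-Regularized Cox Regression for Gene Expression Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Cox proportional hazards models to high-dimensional gene
    expression data with a graph-Laplacian network penalty that encourages
    smooth regression coefficients across a weighted gene relation network.
    Provides primal (Newton-Raphson) and dual (n-dimensional) solvers with a
    Breslow baseline hazard, cross-validated partial likelihood (CVPL) model
    selection over a (lambda, alpha) grid, construction of mutual-rank gene
    co-expression networks, evaluation via log-rank tests and time-dependent
    ROC curves for censored outcomes, coefficient-magnitude gene rankings with
    consensus lists and overlap curves, network-randomization significance
    assessment, and a synthetic-data generator with modular networks,
    network-smooth coefficients and right-censored proportional-hazards
    event times.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
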