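Package: perturbsem
Title: Causal Structural Equation Models for Cell-Line Perturbation
    Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models cell-line responses to drug perturbations with a linear
    causal structural equation model X = AX + BD + e, where A holds direct
    causal effects among measured responses (proteins, phenotypes) and B the
    direct drug-target effects. Provides two estimators of the mean response
    under intervention: ordinary linear regression of responses on drug
    concentrations (LR), and causal structure regression (CSR), which
    regresses responses on the known direct intervention effects g(D) = BD
    and thereby recovers the total-effect matrix T = (I - A)^-1 and the
    structure matrix A itself. Includes the linear Cellbox ordinary
    differential equation model dx/dt = Wx + u, its closed-form steady state
    -W^-1 u, and the exact reparameterization A = W + I linking it to CSR.
    Ships a fully specified synthetic-data generator for a five-response,
    fifteen-drug benchmark network, random-fold and leave-one-drug-out
    validation harnesses, pooled correlation and mean-absolute-error metrics,
    and a command-line interface for simulation, fitting and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
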