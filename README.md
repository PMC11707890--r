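# perturbsem

Causal structural equation models for predicting cell-line responses to
drug perturbations.

In perturbation panels, cells are treated with drugs (alone or in
combination) and responses — protein levels, phenotypes — are measured as
changes from the unperturbed state. Only a small fraction of possible
perturbations can be tested, so the scientifically valuable question is
extrapolation: can a model trained on some drugs predict the response to a
drug it has never seen applied? `perturbsem` is for computational
biologists and methodologists who want to study exactly that question with
transparent linear models.

## The model

Responses follow a linear structural equation model

    X = A X + B D + e,        E[X | do(D)] = (I - A)^-1 B D

where `A[j,k]` is the direct causal effect of response `k` on response `j`,
column `d` of `B` holds drug `d`'s direct targets and strengths, and `e` is
exogenous noise propagated through the network. Two estimators of the mean
response are provided:

* **LR** — ordinary (optionally lasso-penalized) regression of `X` on `D`,
  estimating the composite map `R = (I - A)^-1 B`. Needs no drug-target
  knowledge; cannot extrapolate to unseen drugs.
* **CSR** — regression of `X` on the known intervention effects
  `g(D) = B D`, estimating the total-effect matrix `T = (I - A)^-1` and
  the causal structure `A = I - T^-1`. Extrapolates to unseen drugs
  whenever the training drugs jointly target every response; sensitive to
  a wrong `B`.

The package also implements the linear Cellbox ODE `dx/dt = W x + u`,
whose steady state is `-W^-1 u`, and the exact equivalence `A = W + I`
linking it to CSR — so Cellbox fitting, prediction and network recovery
are available without any ODE solver in the loop. A fully specified
synthetic benchmark (5 responses, 15 drugs, all 105 two-drug combinations)
plus random-fold and leave-one-drug-out validation harnesses make every
claim testable offline.

## Worked example

```r
library(perturbsem)

sem  <- benchmark_sem()                                   # benchmark ground truth
data <- simulate(sem, seed = 1,
                 design = all_pairs_design(15, sem$drug_names))
fit  <- fit_csr(data, B = sem$B)
round(fit$A_hat, 2)
#>      X1   X2    X3    X4    X5
#> X1 0.00 0.02  0.06 -0.03  0.01
#> X2 1.61 0.02  0.02 -0.02 -0.01
#> X3 1.19 0.00 -0.02  0.01 -0.01
#> X4 0.00 0.01  2.04 -0.02 -0.01
#> X5 0.00 0.00 -0.07  0.03 -0.02
```

The recovered structure matrix reproduces the generating network — direct
effects 1.6 (X1 on X2), 1.2 (X1 on X3) and 2.0 (X3 on X4), all other
entries near zero — from noisy data (noise sd 0.1).

The three-setting estimator comparison:

```r
run_benchmark_experiment(seed = 1)$summary
#>  estimator             split pearson_r       mae n_test
#>         LR                RF 0.9688645 0.1736447     35
#>        CSR                RF 0.9777044 0.1411735     35
#>         LR RF-misspecified-B 0.9688645 0.1736447     35
#>        CSR RF-misspecified-B 0.9292642 0.2398470     35
#>         LR              LODO 0.8055718 0.5100899     35
#>        CSR              LODO 0.9778483 0.1422819     35
```

Reading the table: both estimators predict held-out random-fold conditions
well; misspecifying the drug-target matrix hurts CSR but leaves LR's
predictions bitwise identical (it never uses `B`); and under
leave-one-drug-out extrapolation CSR retains its accuracy while LR — which
must assume the held-out drug has no effect — degrades.

A command-line interface covering simulation, fitting, prediction and
validation is installed at
`system.file("cli", "perturbsem", package = "perturbsem")`; see
`?psem_main`.

## Package layout

* `R/sem.R` — the causal SEM type, interventional mean, total-effect
  matrix, validity reports, network export.
* `R/synthetic.R` — benchmark SEM, all-pairs design, seeded simulation,
  drug-target misspecification.
* `R/estimators.R` — LR and CSR (closed-form and penalized) with rank
  diagnostics.
* `R/cellbox.R` — linear Cellbox ODE, steady states, CSR equivalence.
* `R/validation.R` — splits, metrics, the six-panel benchmark, repeated
  random-fold averaging.
* `R/io.R`, `R/cli.R` — CSV/JSON/YAML round-trips and the CLI.
* `vignettes/causal-perturbation-modeling.Rmd` — model, assumptions,
  numerical choices, limitations.
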