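test_that("unpenalized LR recovers the total drug-effect map on noiseless data", {
  orc <- oracle_benchmark()
  data0 <- noiseless_benchmark_data()
  fit <- fit_lr(data0)
  expect_lt(max(abs(unname(fit$R) - orc$T %*% orc$B)), 1e-8)

  # predictions interpolate the training data exactly
  expect_lt(max(abs(predict(fit, data0$D) - data0$X)), 1e-8)
  # single held-out drug: same total-effect oracle as mean_response
  expect_equal(unname(drop(predict(fit, c(1, rep(0, 14))))),
               c(1, 1.6, 1.2, 2.4, 0), tolerance = 1e-8)
  expect_equal(unname(predict(fit, matrix(0, 2, 15))),
               matrix(0, 2, 5))

  # identity truth: X = D gives R = I
  D <- with_seed_helper(2, matrix(rnorm(60), 20, 3))
  rownames(D) <- paste0("c", 1:20)
  ident <- fit_lr(perturbation_dataset(D, D))
  expect_equal(unname(ident$R), diag(3), tolerance = 1e-10)
})

test_that("zeroed drugs give zero coefficients and zero predictions", {
  data <- simulate(benchmark_sem(), seed = 5, design = all_pairs_design(15))
  fit <- fit_lr(data, zeroed_drugs = "D3")
  expect_true(all(fit$R[, "D3"] == 0))
  only_d3 <- replace(rep(0, 15), 3, 1)
  expect_equal(unname(drop(predict(fit, only_d3))), rep(0, 5))
  expect_error(fit_lr(data, zeroed_drugs = "nope"), "not in dataset")
})

test_that("unpenalized fits refuse rank-deficient designs, naming columns", {
  data <- noiseless_benchmark_data()
  # remove every condition using drug 2: its column is identically zero
  keep <- data$condition_ids[data$D[, "D2"] == 0]
  sub <- subset_conditions(data, keep)
  expect_error(fit_lr(sub), "D2")
  # the minimum-norm escape hatch fits without error
  expect_silent(fit_lr(sub, allow_minimum_norm = TRUE))
  # zeroing the dead column restores a unique fit
  expect_silent(fit_lr(sub, zeroed_drugs = "D2"))
})

test_that("lasso LR matches an independent solver and shrinks to zero", {
  skip_if_not_installed("glmnet")
  D <- with_seed_helper(8, matrix(rnorm(40 * 6), 40, 6))
  rownames(D) <- paste0("c", 1:40)
  R_true <- with_seed_helper(9, matrix(rnorm(12, sd = 1), 2, 6))
  X <- tcrossprod(D, R_true) + with_seed_helper(10, matrix(rnorm(80, sd = 0.2), 40, 2))
  data <- perturbation_dataset(D, X)

  lambda <- 8
  fit <- fit_lr(data, lambda = lambda)
  # glmnet solves (1/2n)||y - Zb||^2 + lam|b|; our objective is
  # ||y - Zb||^2 + lambda|b|, so lam_glmnet = lambda / (2n)
  for (j in 1:2) {
    g <- glmnet::glmnet(D, X[, j], lambda = lambda / (2 * nrow(D)),
                        intercept = FALSE, standardize = FALSE,
                        thresh = 1e-14)
    expect_equal(unname(fit$R[j, ]), as.numeric(g$beta), tolerance = 1e-6)
  }

  # overwhelming penalty zeroes every coefficient
  expect_true(all(fit_lr(data, lambda = 1e6)$R == 0))
})

test_that("unpenalized CSR recovers the structure matrix from noiseless data", {
  orc <- oracle_benchmark()
  data0 <- noiseless_benchmark_data()
  fit <- fit_csr(data0, orc$B)
  expect_lt(max(abs(unname(fit$A_hat) - orc$A)), 1e-8)
  expect_lt(max(abs(unname(fit$T) - orc$T)), 1e-8)
  # A_hat and T are mutually consistent
  expect_lt(max(abs((diag(5) - fit$A_hat) %*% fit$T - diag(5))), 1e-8)
  expect_true(fit$pd_report$positive_definite)

  # unconnected truth: T = I, A_hat = 0
  D <- with_seed_helper(3, matrix(rbinom(80, 1, 0.5) * runif(80), 20, 4))
  rownames(D) <- paste0("c", 1:20)
  B <- diag(4)
  sem_flat <- causal_sem(matrix(0, 4, 4), B, noise_sd = 0)
  flat <- simulate(sem_flat, seed = 2, design = D)
  fit_flat <- fit_csr(flat, B)
  expect_equal(unname(fit_flat$T), diag(4), tolerance = 1e-8)
  expect_equal(unname(fit_flat$A_hat), matrix(0, 4, 4), tolerance = 1e-8)
})

test_that("CSR under a misspecified B recovers a distorted structure", {
  orc <- oracle_benchmark()
  data0 <- noiseless_benchmark_data()
  fit_bad <- suppressWarnings(fit_csr(data0, misspecify_b(orc$B)))
  expect_gt(max(abs(unname(fit_bad$A_hat) - orc$A)), 0.2)
  # oracle route: closed-form OLS with the wrong covariates gives the same T
  G_bad <- tcrossprod(data0$D, misspecify_b(orc$B))
  T_oracle <- t(qr.coef(qr(G_bad), data0$X))
  expect_equal(unname(fit_bad$T), unname(T_oracle), tolerance = 1e-8)
})

test_that("CSR prediction extrapolates through the intervention map", {
  orc <- oracle_benchmark()
  data0 <- noiseless_benchmark_data()
  fit <- fit_csr(data0, orc$B)
  # drug 1 alone was never a training condition (all-pairs only)
  expect_equal(unname(drop(predict(fit, c(1, rep(0, 14))))),
               c(1, 1.6, 1.2, 2.4, 0), tolerance = 1e-8)
  expect_equal(unname(predict(fit, matrix(0, 3, 15))), matrix(0, 3, 5))

  # with T = I the prediction is just B D
  ident <- fit
  ident$T <- diag(5)
  D <- with_seed_helper(4, matrix(runif(30), 2, 15))
  expect_equal(unname(predict(ident, D)), unname(tcrossprod(D, orc$B)))
})

test_that("CSR rank condition is about targeting responses, not using drugs", {
  orc <- oracle_benchmark()
  data0 <- noiseless_benchmark_data()
  # drop all conditions using drug 1: every response is still targeted by
  # the remaining drugs, so CSR fits (this is the LODO extrapolation point)
  sub <- subset_conditions(data0, data0$condition_ids[data0$D[, 1] == 0])
  expect_silent(fit <- fit_csr(sub, orc$B))
  expect_lt(max(abs(unname(fit$A_hat) - orc$A)), 1e-8)

  # but a B whose rows never touch response 5 is rank deficient
  B_gap <- orc$B
  B_gap[5, ] <- 0
  expect_error(fit_csr(noiseless_benchmark_data(), B_gap), "target every response")
})

test_that("closed-form fits minimize the stated least-squares objectives", {
  # small random instances, generic numerical minimizer as the oracle
  for (seed in 1:4) {
    p <- 3; q <- 6; n <- 20
    A <- with_seed_helper(seed, {
      A <- matrix(0, p, p)
      A[lower.tri(A)] <- runif(p * (p - 1) / 2, -0.8, 0.8)
      A
    })
    B <- with_seed_helper(seed + 50, matrix(rbinom(p * q, 1, 0.4) * runif(p * q), p, q))
    if (qr(B)$rank < p) next
    sem <- causal_sem(A, B, noise_sd = 0.05)
    D <- with_seed_helper(seed + 100, matrix(rbinom(n * q, 1, 0.5), n, q))
    rownames(D) <- paste0("c", 1:n)
    data <- simulate(sem, seed = seed + 150, design = D)

    lr <- fit_lr(data)
    expect_equal(unname(lr$R), oracle_minimize_ls(data$D, data$X),
                 tolerance = 1e-5)
    csr <- fit_csr(data, B)
    expect_equal(unname(csr$T),
                 oracle_minimize_ls(tcrossprod(data$D, B), data$X),
                 tolerance = 1e-5)
  }
})

test_that("parameter recovery across seeded replicates of the benchmark", {
  sem <- benchmark_sem()
  design <- all_pairs_design(15, sem$drug_names)
  entries <- array(NA_real_, c(50, 5, 5))
  for (r in 1:50) {
    data <- simulate(sem, seed = derive_seed(99, r), design = design)
    split <- random_fold_split(data, 2 / 3, seed = derive_seed(199, r))
    fit <- fit_csr(subset_conditions(data, split$train_ids), sem$B)
    entries[r, , ] <- fit$A_hat
  }
  mean_A <- apply(entries, c(2, 3), mean)
  expect_lt(abs(mean_A[2, 1] - 1.6), 0.05)
  expect_lt(abs(mean_A[3, 1] - 1.2), 0.05)
  expect_lt(abs(mean_A[4, 3] - 2.0), 0.05)
  zero_mask <- unname(benchmark_sem()$A) == 0
  diag(zero_mask) <- FALSE
  expect_lt(max(abs(mean_A[zero_mask])), 0.05)
})

test_that("penalized CSR approaches the closed form as the penalty vanishes", {
  orc <- oracle_benchmark()
  data0 <- noiseless_benchmark_data()
  exact <- fit_csr(data0, orc$B)
  pen <- fit_csr_penalized(data0, orc$B, lambda = 1e-8)
  expect_lt(max(abs(pen$A_hat - exact$A_hat)), 1e-3)
  expect_true(is.finite(pen$objective))
})

test_that("penalized CSR honors overwhelming penalties and masks", {
  sem <- benchmark_sem()
  data <- simulate(sem, seed = 31, design = all_pairs_design(15))
  big <- fit_csr_penalized(data, sem$B, lambda = 1e6)
  off <- big$A_hat
  diag(off) <- 0
  expect_true(all(off == 0))

  mask <- matrix(0, 5, 5)
  mask[2, 1] <- 1
  masked <- fit_csr_penalized(noiseless_benchmark_data(), sem$B, lambda = 1,
                              mask = mask)
  expect_identical(masked$A_hat[2, 1], 0)
  # other true edges survive the constraint
  expect_gt(masked$A_hat[4, 3], 1.5)
})

test_that("both estimators reproduce the mean response exactly at the truth", {
  orc <- oracle_benchmark()
  data0 <- noiseless_benchmark_data()
  lr <- fit_lr(data0)
  csr <- fit_csr(data0, orc$B)
  D_te <- with_seed_helper(77, matrix(rbinom(10 * 15, 1, 0.3) * runif(150), 10, 15))
  truth <- t(apply(D_te, 1, function(d) mean_response(benchmark_sem(), d)))
  expect_lt(max(abs(predict(lr, D_te) - truth)), 1e-8)
  expect_lt(max(abs(predict(csr, D_te) - truth)), 1e-8)
})
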