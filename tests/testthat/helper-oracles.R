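# Independent oracles used across the suite. These rebuild the benchmark
# matrices by hand and compute expected values by routes that do not touch
# the package's own code paths.

# Benchmark ground truth written out entry by entry.
oracle_benchmark <- function() {
  A <- matrix(0, 5, 5)
  A[2, 1] <- 1.6
  A[3, 1] <- 1.2
  A[4, 3] <- 2
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 3),
                c(2, 4), c(2, 5), c(3, 4), c(3, 5), c(4, 5))
  B <- diag(5)
  for (jk in pairs) {
    col <- numeric(5)
    col[jk] <- 0.5
    B <- cbind(B, col)
  }
  dimnames(B) <- NULL
  # A is nilpotent (DAG, A^3 = 0), so the Neumann series terminates:
  Ttrue <- diag(5) + A + A %*% A
  list(A = A, B = B, T = Ttrue, noise_sd = 0.1)
}

# Generic numerical minimizer of the multi-response least-squares objective
# sum_i ||X_i - C Z_i||^2 over C, by BFGS from zero start. Used to confirm
# the closed-form fits solve the stated objective.
oracle_minimize_ls <- function(Z, X) {
  pz <- ncol(Z)
  px <- ncol(X)
  obj <- function(theta) {
    C <- matrix(theta, px, pz)
    sum((X - tcrossprod(Z, C))^2)
  }
  res <- optim(numeric(px * pz), obj, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-14))
  matrix(res$par, px, pz)
}

# Brute-force evaluation of the Cellbox steady-state objective
# sum_i ||X_i - (-W^-1) g_i||^2 + lambda ||W - diag(W)||_1, used as an
# oracle that the reparameterized fit actually minimizes it.
oracle_cellbox_objective <- function(W, G, X, lambda = 0) {
  pred <- tcrossprod(G, -solve(W))
  off <- W
  diag(off) <- 0
  sum((X - pred)^2) + lambda * sum(abs(off))
}

# Noiseless benchmark dataset: every row is the exact mean response.
noiseless_benchmark_data <- function() {
  sem <- causal_sem(oracle_benchmark()$A, oracle_benchmark()$B, noise_sd = 0)
  simulate(sem, seed = 1,
           design = all_pairs_design(15, sem$drug_names))
}

# Random dataset of the Melanoma shape (89 conditions, 12 drugs,
# 87 responses) from a random stable linear SEM; synthetic stand-in used
# only to exercise protocol plumbing at realistic dimensions.
synthetic_melanoma_shape <- function(seed = 42) {
  p <- 87L
  q <- 12L
  n <- 89L
  A <- with_seed_helper(seed, {
    A <- matrix(0, p, p)
    idx <- sample(which(row(A) != col(A)), 150)
    A[idx] <- runif(150, -0.4, 0.4)
    A
  })
  B <- with_seed_helper(seed + 1, {
    B <- matrix(0, p, q)
    for (j in seq_len(q)) B[sample(p, 3), j] <- runif(3, 0.5, 1.5)
    B
  })
  D <- with_seed_helper(seed + 2, {
    D <- matrix(0, n, q)
    for (i in seq_len(n)) {
      k <- sample(1:2, 1)
      D[i, sample(q, k)] <- exp(rnorm(k, 0, 0.5))
    }
    D
  })
  sem <- causal_sem(A, B, noise_sd = 0.1)
  simulate(sem, seed = seed + 3, design = D)
}

with_seed_helper <- function(seed, code) withr::with_seed(seed, code)

# Minimal hand-built split for error-path tests.
new_split_for_test <- function(data) {
  structure(list(train_ids = data$condition_ids[1],
                 test_ids = data$condition_ids[-1],
                 held_out_drug = NA_character_, kind = "random_fold"),
            class = "split_spec")
}
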