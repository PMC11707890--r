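#' The five-response, fifteen-drug benchmark SEM
#'
#' Returns the fully specified ground-truth model used throughout the
#' package's simulations: p = 5 responses, q = 15 drugs. Drugs 1-5 each
#' target a single response with strength 1 (B columns 1-5 are the
#' identity); drugs 6-15 each target two responses with strength 0.5,
#' covering all 10 response pairs in lexicographic order
#' (1,2), (1,3), (1,4), (1,5), (2,3), (2,4), (2,5), (3,4), (3,5), (4,5).
#' Among responses, X1 has a direct causal effect of 1.6 on X2 and 1.2 on
#' X3, and X3 an effect of 2 on X4; all other direct effects are zero, so A
#' is a DAG and `(I - A)^-1 = I + A + A^2` exactly. Exogenous errors are
#' N(0, 0.1^2).
#'
#' The lexicographic completion of the two-target column pattern is an
#' assumption of this module: the first five two-target columns and the last
#' are pinned by the published pattern, and structure recovery is invariant
#' to the ordering of the remaining pairs because the all-pairs design keeps
#' the intervention covariates full rank.
#'
#' @return A [causal_sem()] with `p = 5`, `q = 15`, `noise_sd = 0.1`.
#' @examples
#' sem <- benchmark_sem()
#' mean_response(sem, c(1, rep(0, 14)))  # drug 1 alone: (1, 1.6, 1.2, 2.4, 0)
#' @export
benchmark_sem <- function() {
  p <- 5L
  A <- matrix(0, p, p)
  A[2, 1] <- 1.6
  A[3, 1] <- 1.2
  A[4, 3] <- 2
  pairs <- utils::combn(p, 2)
  B <- cbind(diag(p), apply(pairs, 2, function(jk) {
    col <- numeric(p)
    col[jk] <- 0.5
    col
  }))
  causal_sem(A, B, noise_sd = 0.1,
             response_names = paste0("X", 1:p),
             drug_names = paste0("D", 1:15))
}

#' All-pairs two-drug design matrix
#'
#' Every possible combination of two drugs at unit concentration: q(q-1)/2
#' conditions in lexicographic pair order (1,2), (1,3), ..., (q-1,q), each
#' row with exactly two entries equal to 1.
#'
#' @param q number of drugs (at least 2).
#' @param drug_names optional drug names (length q).
#' @return A list of class `design_matrix` with elements `D` (n x q matrix),
#'   `drug_names`, `condition_ids` (`"drugA+drugB"` strings).
#' @examples
#' d <- all_pairs_design(15)
#' nrow(d$D)  # 105
#' @export
all_pairs_design <- function(q, drug_names = NULL) {
  if (!is.numeric(q) || length(q) != 1L || q < 2 || q != round(q)) {
    stop("q must be an integer >= 2", call. = FALSE)
  }
  q <- as.integer(q)
  drug_names <- drug_names %||% paste0("D", seq_len(q))
  check_length(drug_names, q, "drug_names")
  pairs <- utils::combn(q, 2)
  D <- matrix(0, ncol(pairs), q)
  D[cbind(seq_len(ncol(pairs)), pairs[1, ])] <- 1
  D[cbind(seq_len(ncol(pairs)), pairs[2, ])] <- 1
  ids <- paste(drug_names[pairs[1, ]], drug_names[pairs[2, ]], sep = "+")
  dimnames(D) <- list(ids, drug_names)
  structure(list(D = D, drug_names = as.character(drug_names),
                 condition_ids = ids),
            class = "design_matrix")
}

#' Simulate perturbation responses from a causal SEM
#'
#' For each design row `D_i`, draws an error vector from the model's noise
#' distribution and returns the response solving `(I - A) X_i = B D_i + e_i`.
#' Noise therefore propagates through the causal network — the observed
#' error is `(I - A)^-1 e_i`, not `e_i` added to the mean. Independent
#' N(0, noise_sd^2) elements by default; a full `noise_cov` draws correlated
#' errors (hidden confounding).
#'
#' @param object a [causal_sem()].
#' @param nsim number of datasets to generate (default 1).
#' @param seed integer seed; required, so that every stochastic operation is
#'   explicitly reproducible and no hidden global RNG state is consumed.
#' @param design a `design_matrix` from [all_pairs_design()], or a bare
#'   numeric n x q matrix.
#' @param ... unused.
#' @return A [perturbation_dataset()] (or a list of them when `nsim > 1`).
#' @examples
#' data <- simulate(benchmark_sem(), seed = 1, design = all_pairs_design(15))
#' @export
simulate.causal_sem <- function(object, nsim = 1, seed, design, ...) {
  if (missing(seed) || is.null(seed)) {
    stop("an explicit integer seed is required", call. = FALSE)
  }
  if (inherits(design, "design_matrix")) {
    D <- design$D
    ids <- design$condition_ids
  } else {
    D <- as_numeric_matrix(design, "design")
    ids <- rownames(D)
  }
  q <- length(object$drug_names)
  if (ncol(D) != q) {
    stop(sprintf("design has %d columns, expected %d drugs", ncol(D), q),
         call. = FALSE)
  }
  p <- length(object$response_names)
  n <- nrow(D)
  ImA <- diag(p) - object$A
  mean_part <- tcrossprod(D, object$B)  # n x p: rows are (B D_i)'
  datasets <- with_seed(seed, lapply(seq_len(nsim), function(k) {
    E <- if (is.null(object$noise_cov)) {
      matrix(stats::rnorm(n * p, sd = object$noise_sd), n, p)
    } else {
      L <- t(chol(object$noise_cov))
      t(L %*% matrix(stats::rnorm(n * p), p, n))
    }
    X <- t(solve(ImA, t(mean_part + E)))
    perturbation_dataset(D, X, drug_names = object$drug_names,
                         response_names = object$response_names,
                         condition_ids = ids)
  }))
  if (nsim == 1) datasets[[1]] else datasets
}

#' Misspecify a direct-effect matrix B
#'
#' Replaces every entry equal to 0.5 with 1, leaving other entries
#' untouched — the scenario in which two-target drugs are wrongly believed
#' to hit each target at full strength. Used to probe the sensitivity of
#' structure-based estimators to wrong drug-target knowledge.
#'
#' @param B p x q numeric matrix; entries are expected to lie in
#'   \{0, 0.5, 1\} (a warning is issued otherwise).
#' @return A copy of B with all 0.5 entries set to 1.
#' @export
misspecify_b <- function(B) {
  B <- as_numeric_matrix(B, "B")
  if (!all(B %in% c(0, 0.5, 1))) {
    warning("B has entries outside {0, 0.5, 1}; only 0.5 entries are changed")
  }
  B[B == 0.5] <- 1
  B
}
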