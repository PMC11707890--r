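#' Construct a causal structural equation model for perturbation responses
#'
#' The model is `X = A X + g(D) + e` with linear intervention map
#' `g(D) = B D`. Entry `A[j, k]` is the direct causal effect of a one-unit
#' change in response `k` on response `j`; column `d` of `B` holds the direct
#' (first-hit) effects of drug `d` on the responses. Errors `e` are mean-zero
#' with standard deviation `noise_sd` per element; an optional full covariance
#' `noise_cov` models hidden confounding among responses (unmeasured common
#' causes such as cell cycle or batch conditions).
#'
#' @param A p x p numeric matrix of direct effects among responses.
#' @param B p x q numeric matrix of direct drug effects.
#' @param noise_sd nonnegative scalar; per-element error standard deviation.
#' @param response_names,drug_names optional character vectors (length p, q).
#' @param noise_cov optional p x p positive semi-definite error covariance;
#'   overrides `noise_sd` when supplied.
#' @param rcond_min smallest acceptable reciprocal condition number of
#'   `I - A`; below this the model is rejected as numerically singular.
#' @return An object of class `causal_sem` with elements `A`, `B`,
#'   `noise_sd`, `noise_cov`, `response_names`, `drug_names`.
#' @examples
#' sem <- causal_sem(A = matrix(0, 2, 2), B = diag(2), noise_sd = 0.1)
#' mean_response(sem, c(1, 0))
#' @export
causal_sem <- function(A, B, noise_sd = 0, response_names = NULL,
                       drug_names = NULL, noise_cov = NULL,
                       rcond_min = 1e-12) {
  A <- as_numeric_matrix(A, "A")
  B <- as_numeric_matrix(B, "B")
  p <- nrow(A)
  if (ncol(A) != p) stop("A must be square", call. = FALSE)
  if (nrow(B) != p) {
    stop(sprintf("B has %d rows, expected %d (one per response)",
                 nrow(B), p), call. = FALSE)
  }
  q <- ncol(B)
  stopifnot(is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0)
  response_names <- response_names %||% paste0("X", seq_len(p))
  drug_names <- drug_names %||% paste0("D", seq_len(q))
  check_length(response_names, p, "response_names")
  check_length(drug_names, q, "drug_names")
  if (!is.null(noise_cov)) {
    noise_cov <- as_numeric_matrix(noise_cov, "noise_cov")
    if (!all(dim(noise_cov) == c(p, p))) {
      stop("noise_cov must be p x p", call. = FALSE)
    }
    if (max(abs(noise_cov - t(noise_cov))) > 1e-10) {
      stop("noise_cov must be symmetric", call. = FALSE)
    }
  }
  ImA <- diag(p) - A
  rc <- rcond(ImA)
  if (!is.finite(rc) || rc < rcond_min) {
    stop(sprintf(
      "I - A is numerically singular (reciprocal condition number %.3g < %.3g)",
      rc, rcond_min), call. = FALSE)
  }
  dimnames(A) <- list(response_names, response_names)
  dimnames(B) <- list(response_names, drug_names)
  structure(
    list(A = A, B = B, noise_sd = noise_sd, noise_cov = noise_cov,
         response_names = as.character(response_names),
         drug_names = as.character(drug_names)),
    class = "causal_sem")
}

#' @export
print.causal_sem <- function(x, ...) {
  cat(sprintf("Causal SEM: %d responses, %d drugs, noise sd %g%s\n",
              length(x$response_names), length(x$drug_names), x$noise_sd,
              if (is.null(x$noise_cov)) "" else " (full noise covariance)"))
  nz <- which(x$A != 0, arr.ind = TRUE)
  cat(sprintf("  %d nonzero direct effects among responses\n", nrow(nz)))
  invisible(x)
}

#' Mean response under intervention
#'
#' Computes the interventional mean `E[X | do(D)] = (I - A)^-1 B D` — the
#' prediction target for perturbation experiments. Because drug concentrations
#' are set by the experimenter, no backdoor paths from D to X exist and the
#' interventional and observational means coincide.
#'
#' @param sem a [causal_sem()].
#' @param D numeric vector of drug concentrations (length q).
#' @return Numeric vector of p expected responses, named by response.
#' @export
mean_response <- function(sem, D) {
  stopifnot(inherits(sem, "causal_sem"))
  D <- as.numeric(D)
  q <- length(sem$drug_names)
  if (length(D) != q) {
    stop(sprintf("D has length %d, expected %d drugs", length(D), q),
         call. = FALSE)
  }
  p <- length(sem$response_names)
  x <- solve(diag(p) - sem$A, sem$B %*% D)
  stats::setNames(drop(x), sem$response_names)
}

#' Total-effect matrix T = (I - A)^-1
#'
#' Entry `(j, k)` of T is the total effect — direct plus all mediated paths —
#' of response k on response j at equilibrium. For a DAG structure A the
#' Neumann series `I + A + A^2 + ...` terminates and equals T.
#'
#' @param sem a [causal_sem()].
#' @return p x p numeric matrix with response names on both dimensions.
#' @export
total_effect_matrix <- function(sem) {
  stopifnot(inherits(sem, "causal_sem"))
  p <- length(sem$response_names)
  T_ <- tryCatch(solve(diag(p) - sem$A),
                 error = function(e) stop("I - A is singular", call. = FALSE))
  dimnames(T_) <- list(sem$response_names, sem$response_names)
  T_
}

# Positive-definiteness verdict for a (possibly non-symmetric) matrix M.
# mode "real-eigenvalue": all eigenvalues of M have positive real part
#   (the stability condition of the companion ODE system);
# mode "symmetric-part": all eigenvalues of (M + M')/2 positive
#   (the quadratic-form definition).
pd_verdict <- function(M, mode = c("real-eigenvalue", "symmetric-part")) {
  mode <- match.arg(mode)
  ev <- if (mode == "symmetric-part") {
    eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  } else {
    Re(eigen(M, only.values = TRUE)$values)
  }
  list(positive_definite = all(ev > 0), mode = mode,
       min_eigenvalue = min(ev))
}

# TRUE when A is permutable to strict triangularity, i.e. a weighted DAG
# adjacency. Topological peel: repeatedly remove nodes with no incoming
# direct effects (A[j, k] != 0 means k -> j, so row j lists j's parents).
is_dag_matrix <- function(A, tol = 0) {
  M <- abs(A) > tol
  diag(M) <- FALSE
  remaining <- seq_len(nrow(M))
  repeat {
    if (length(remaining) == 0L) return(TRUE)
    sub <- M[remaining, remaining, drop = FALSE]
    no_parents <- which(rowSums(sub) == 0)
    if (length(no_parents) == 0L) return(FALSE)
    remaining <- remaining[-no_parents]
  }
}

#' Structural validity report for a causal SEM
#'
#' Checks (a) invertibility of `I - A` at a reciprocal-condition-number
#' threshold, (b) positive definiteness of `I - A` under a chosen convention
#' for non-symmetric matrices, and (c) acyclicity of the direct-effect
#' structure. Positive definiteness of a non-symmetric matrix is
#' convention-dependent, so two modes are offered: `"real-eigenvalue"`
#' (default; all eigenvalue real parts positive — exactly the condition for
#' the companion linear ODE to converge to its steady state) and
#' `"symmetric-part"` (all eigenvalues of the symmetrized matrix positive).
#' The report records which mode was used. This is a report, not a gate: no
#' error is thrown for failing verdicts.
#'
#' @param sem a [causal_sem()].
#' @param pd_mode `"real-eigenvalue"` or `"symmetric-part"`.
#' @param rcond_min invertibility threshold on the reciprocal condition number.
#' @return A list of class `sem_validity` with elements `invertible`,
#'   `rcond`, `pd` (verdict list), `acyclic`.
#' @export
validate_sem <- function(sem, pd_mode = c("real-eigenvalue", "symmetric-part"),
                         rcond_min = 1e-12) {
  stopifnot(inherits(sem, "causal_sem"))
  pd_mode <- match.arg(pd_mode)
  p <- length(sem$response_names)
  ImA <- diag(p) - sem$A
  rc <- rcond(ImA)
  structure(
    list(invertible = is.finite(rc) && rc > rcond_min,
         rcond = rc,
         pd = pd_verdict(ImA, pd_mode),
         acyclic = is_dag_matrix(sem$A)),
    class = "sem_validity")
}

#' @export
print.sem_validity <- function(x, ...) {
  cat(sprintf(
    "I - A invertible: %s (rcond %.3g)\npositive definite [%s]: %s\nacyclic: %s\n",
    x$invertible, x$rcond, x$pd$mode, x$pd$positive_definite, x$acyclic))
  invisible(x)
}

#' Export the direct-effect network as an edge list
#'
#' One row per off-diagonal nonzero entry of A with `|weight|` at or above
#' the display threshold, with columns `source`, `target`, `weight`
#' (`A[j, k]` becomes the edge `k -> j`). The default threshold 0.2 suppresses
#' small coefficients, the usual convention for network displays of fitted
#' structure matrices.
#'
#' @param A p x p structure matrix (or a `causal_sem`, whose A is used).
#' @param threshold minimum absolute weight to include.
#' @param names response names; defaults to rownames of A.
#' @return A data.frame with columns source, target, weight.
#' @export
network_edges <- function(A, threshold = 0.2, names = NULL) {
  if (inherits(A, "causal_sem")) {
    names <- names %||% A$response_names
    A <- A$A
  }
  A <- as_numeric_matrix(A, "A")
  names <- names %||% rownames(A) %||% paste0("X", seq_len(nrow(A)))
  off <- A
  diag(off) <- 0
  idx <- which(abs(off) >= threshold, arr.ind = TRUE)
  edges <- data.frame(source = names[idx[, "col"]],
                      target = names[idx[, "row"]],
                      weight = off[idx],
                      stringsAsFactors = FALSE)
  edges[order(edges$source, edges$target), , drop = FALSE]
}
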