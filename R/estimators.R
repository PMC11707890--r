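#' Fit the linear-regression (LR) estimator
#'
#' Regresses each response on the drug concentrations:
#' `min_R sum_i ||X_i - R D_i||^2 + lambda * sum |R_jk|`, estimating the
#' p x q map `R = (I - A)^-1 B` without any drug-target knowledge. With
#' `lambda = 0` each response row is an exact least-squares fit; with
#' `lambda > 0` a lasso penalty on all entries of R is solved by cyclic
#' coordinate descent. No intercept is fitted: responses are changes
#' relative to the unperturbed state.
#'
#' Drugs named in `zeroed_drugs` have their coefficient column forced to 0
#' and are excluded from the regression — the leave-one-drug-out convention
#' in which a held-out drug is assumed (crudely) to have no effect. An
#' unpenalized fit on a rank-deficient drug design is refused with an error
#' naming the offending columns, because the minimizer is then not unique;
#' `allow_minimum_norm = TRUE` opts into the minimum-norm solution for
#' exploratory use.
#'
#' @param data a [perturbation_dataset()].
#' @param lambda nonnegative lasso penalty weight (0 = ordinary least squares).
#' @param zeroed_drugs character vector of drug names whose coefficients are
#'   forced to zero.
#' @param allow_minimum_norm with `lambda = 0`, fit the minimum-norm solution
#'   instead of erroring on a rank-deficient design.
#' @param center_columns subtract column means of D and X before fitting
#'   (off by default; the model has no intercept).
#' @return An object of class `lr_model` with elements `R` (p x q), `lambda`,
#'   `zeroed_drugs`, `drug_names`, `response_names`.
#' @examples
#' data <- simulate(benchmark_sem(), seed = 1, design = all_pairs_design(15))
#' fit <- fit_lr(data)
#' predict(fit, data$D[1:2, ])
#' @export
fit_lr <- function(data, lambda = 0, zeroed_drugs = character(),
                   allow_minimum_norm = FALSE, center_columns = FALSE) {
  stopifnot(inherits(data, "perturbation_dataset"),
            is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
  zeroed_drugs <- as.character(zeroed_drugs)
  unknown <- setdiff(zeroed_drugs, data$drug_names)
  if (length(unknown) > 0L) {
    stop("zeroed_drugs not in dataset: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- setdiff(data$drug_names, zeroed_drugs)
  D <- data$D[, keep, drop = FALSE]
  X <- data$X
  if (center_columns) {
    D <- scale(D, center = TRUE, scale = FALSE)
    X <- scale(X, center = TRUE, scale = FALSE)
  }
  coef_sub <- fit_multiresponse(D, X, lambda, allow_minimum_norm,
                                design_label = "drug")
  R <- matrix(0, ncol(X), length(data$drug_names),
              dimnames = list(data$response_names, data$drug_names))
  R[, keep] <- coef_sub
  structure(list(R = R, lambda = lambda, zeroed_drugs = zeroed_drugs,
                 drug_names = data$drug_names,
                 response_names = data$response_names),
            class = "lr_model")
}

#' @export
print.lr_model <- function(x, ...) {
  cat(sprintf("LR model: %d responses x %d drugs, lambda = %g%s\n",
              nrow(x$R), ncol(x$R), x$lambda,
              if (length(x$zeroed_drugs))
                paste0(", zeroed: ", paste(x$zeroed_drugs, collapse = ","))
              else ""))
  invisible(x)
}

#' Predict responses from an LR model
#'
#' @param object an `lr_model`.
#' @param D m x q matrix (or length-q vector) of drug concentrations.
#' @param ... unused.
#' @return m x p matrix of predicted mean responses `R D_i`.
#' @export
predict.lr_model <- function(object, D, ...) {
  D <- coerce_design(D, length(object$drug_names), "D")
  out <- tcrossprod(D, object$R)
  colnames(out) <- object$response_names
  out
}

#' Fit the causal structure regression (CSR) estimator
#'
#' Regresses responses on the known direct intervention effects
#' `g(D_i) = B D_i`, estimating the total-effect matrix `T = (I - A)^-1`
#' by least squares: `min_T sum_i ||X_i - T g(D_i)||^2`. When the fitted T
#' is invertible the structure matrix is recovered as `A_hat = I - T^-1`.
#' Because the regressors are intervention effects rather than raw drug
#' columns, CSR can predict responses to drugs absent from training,
#' provided the training drugs jointly target every response variable
#' (the rank condition on the intervention covariates).
#'
#' The fitted T carries a positive-definiteness report rather than being
#' constrained during optimization; a warning is emitted when the check
#' fails. Use [fit_csr_penalized()] for the lasso-penalized structural fit.
#'
#' @param data a [perturbation_dataset()].
#' @param B p x q direct-effect matrix (drug targets and strengths).
#' @param lambda must be 0 here; positive penalties go through
#'   [fit_csr_penalized()].
#' @param pd_mode positive-definiteness convention passed to the T check
#'   (see [validate_sem()]).
#' @param allow_minimum_norm fit the minimum-norm T on a rank-deficient
#'   intervention design instead of erroring.
#' @return An object of class `csr_model` with elements `T` (p x p),
#'   `A_hat` (p x p, or NULL when T is singular), `pd_report`, `lambda`,
#'   `B`, `drug_names`, `response_names`.
#' @examples
#' sem <- benchmark_sem()
#' data <- simulate(sem, seed = 1, design = all_pairs_design(15))
#' fit <- fit_csr(data, B = sem$B)
#' round(fit$A_hat, 2)
#' @export
fit_csr <- function(data, B, lambda = 0,
                    pd_mode = c("real-eigenvalue", "symmetric-part"),
                    allow_minimum_norm = FALSE) {
  stopifnot(inherits(data, "perturbation_dataset"))
  pd_mode <- match.arg(pd_mode)
  if (lambda != 0) {
    stop("penalized CSR fits go through fit_csr_penalized()", call. = FALSE)
  }
  B <- check_b(B, data)
  G <- tcrossprod(data$D, B)  # n x p, rows g(D_i)'
  T_t <- fit_multiresponse(G, data$X, 0, allow_minimum_norm,
                           design_label = "intervention",
                           rank_hint = paste(
                             "the training drugs must directly target every",
                             "response variable"))
  T_ <- T_t
  dimnames(T_) <- list(data$response_names, data$response_names)
  new_csr_model(T_, lambda = 0, B = B, data = data, pd_mode = pd_mode)
}

# Shared CSR model assembly: invert T for A_hat (unless the optimizer
# already produced A directly), attach pd report.
new_csr_model <- function(T_, lambda, B, data, pd_mode,
                          objective = NULL, seed = NULL, mask = NULL,
                          A_hat = NULL) {
  if (is.null(A_hat) && is.finite(rcond(T_)) && rcond(T_) > 1e-12) {
    A_hat <- diag(nrow(T_)) - solve(T_)
  }
  if (!is.null(A_hat)) dimnames(A_hat) <- dimnames(T_)
  pd_report <- pd_verdict(T_, pd_mode)
  if (!pd_report$positive_definite) {
    warning(sprintf(
      "fitted total-effect matrix T fails the positive-definiteness check (%s mode)",
      pd_report$mode), call. = FALSE)
  }
  structure(list(T = T_, A_hat = A_hat, pd_report = pd_report,
                 lambda = lambda, B = B, objective = objective, seed = seed,
                 mask = mask,
                 drug_names = data$drug_names,
                 response_names = data$response_names),
            class = "csr_model")
}

#' @export
print.csr_model <- function(x, ...) {
  cat(sprintf(
    "CSR model: %d responses, lambda = %g, T positive definite [%s]: %s\n",
    nrow(x$T), x$lambda, x$pd_report$mode, x$pd_report$positive_definite))
  invisible(x)
}

#' Predict responses from a CSR model
#'
#' Returns `T B D_i` for each row of D. Because prediction goes through the
#' intervention map, D may use drugs that never appeared in training as long
#' as B covers their direct targets — the leave-one-drug-out extrapolation
#' contract.
#'
#' @param object a `csr_model`.
#' @param D m x q matrix (or length-q vector) of drug concentrations.
#' @param B optional p x q direct-effect matrix; defaults to the B used in
#'   fitting.
#' @param ... unused.
#' @return m x p matrix of predicted mean responses.
#' @export
predict.csr_model <- function(object, D, B = NULL, ...) {
  if (is.null(B)) B <- object$B
  if (is.null(B)) stop("no B available: supply one for prediction", call. = FALSE)
  B <- as_numeric_matrix(B, "B")
  if (nrow(B) != nrow(object$T)) {
    stop(sprintf("B has %d rows, expected %d", nrow(B), nrow(object$T)),
         call. = FALSE)
  }
  D <- coerce_design(D, ncol(B), "D")
  out <- tcrossprod(D, object$T %*% B)
  colnames(out) <- object$response_names
  out
}

#' Fit CSR with a lasso penalty on the off-diagonal structure
#'
#' Minimizes `sum_i ||X_i - (I - A)^-1 g(D_i)||^2 + lambda ||A - diag(A)||_1`
#' over the structure matrix A directly, by proximal gradient descent with
#' backtracking line search: gradient steps on the smooth residual term
#' (via `dT = T dA T` for `T = (I - A)^-1`) followed by soft-thresholding of
#' the off-diagonal entries. Diagonal entries are never penalized. An
#' optional binary `mask` pins entries of A to zero throughout — the
#' mechanism for domain constraints such as forbidding phenotype-to-protein
#' effects. The domain restriction `I - A` positive definite is not enforced
#' during optimization; the returned model carries a `pd_report` on the
#' implied T and warns on failure.
#'
#' @param data a [perturbation_dataset()].
#' @param B p x q direct-effect matrix.
#' @param lambda positive penalty weight.
#' @param mask optional p x p matrix; nonzero (TRUE) entries mark positions
#'   of A constrained to zero.
#' @param seed integer seed, recorded in the model. The solver itself is
#'   deterministic (fixed initialization at A = 0), so the seed does not
#'   alter the fit; it is kept for provenance and interface uniformity.
#' @param pd_mode positive-definiteness convention for the T check.
#' @param max_iter iteration cap.
#' @param tol convergence threshold on the maximum coefficient change.
#' @return A `csr_model` whose `objective` element records the achieved
#'   penalized objective value.
#' @export
fit_csr_penalized <- function(data, B, lambda, mask = NULL, seed = 0,
                              pd_mode = c("real-eigenvalue", "symmetric-part"),
                              max_iter = 100000L, tol = 1e-8) {
  stopifnot(inherits(data, "perturbation_dataset"),
            is.numeric(lambda), length(lambda) == 1L, lambda > 0)
  pd_mode <- match.arg(pd_mode)
  B <- check_b(B, data)
  p <- length(data$response_names)
  G <- tcrossprod(data$D, B)
  X <- data$X
  free <- matrix(TRUE, p, p)
  if (!is.null(mask)) {
    mask <- as_numeric_matrix(mask * 1, "mask")
    if (!all(dim(mask) == c(p, p))) stop("mask must be p x p", call. = FALSE)
    free <- mask == 0
  }
  off_diag <- matrix(TRUE, p, p)
  diag(off_diag) <- FALSE

  objective <- function(A) {
    T_ <- tryCatch(solve(diag(p) - A), error = function(e) NULL)
    if (is.null(T_)) return(list(value = Inf))
    R <- X - tcrossprod(G, T_)  # n x p residuals
    list(value = sum(R^2) + lambda * sum(abs(A[off_diag])), T_ = T_, R = R)
  }
  gradient <- function(A, T_, R) {
    # d/dT of sum ||X_i - T g_i||^2 is -2 R' G; chain through T = (I-A)^-1
    gT <- -2 * crossprod(R, G)
    t(T_) %*% gT %*% t(T_)
  }

  # Proximal gradient with Barzilai-Borwein steps and a non-monotone
  # line search (SpaRSA scheme): BB steps track the local curvature of the
  # ill-conditioned loss surface, and acceptance against the worst of the
  # last few objectives lets them act without being throttled.
  A <- matrix(0, p, p)
  obj <- objective(A)
  grad <- gradient(A, obj$T_, obj$R)
  trace <- numeric(0)
  memory <- 10L
  step <- 1 / max(1, sum(G^2))  # conservative first step
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ref <- max(utils::tail(c(obj$value, trace), memory))
    repeat {
      A_new <- A - step * grad
      A_new[off_diag] <- soft_threshold(A_new[off_diag], step * lambda)
      A_new[!free] <- 0
      obj_new <- objective(A_new)
      if (is.finite(obj_new$value) &&
          obj_new$value <= ref - 1e-10 * sum((A_new - A)^2) / max(step, 1e-12))
        break
      step <- step / 2
      if (step < 1e-300) {
        stop_nonconvergence(trace, "line search underflow")
      }
    }
    grad_new <- gradient(A_new, obj_new$T_, obj_new$R)
    delta <- max(abs(A_new - A))
    dA <- A_new - A
    dG <- grad_new - grad
    bb <- sum(dA * dG)
    step <- if (bb > 0) sum(dA * dA) / bb else step * 2
    A <- A_new
    obj <- obj_new
    grad <- grad_new
    trace <- c(trace, obj$value)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) stop_nonconvergence(trace, "iteration cap reached")
  T_ <- obj$T_
  dimnames(T_) <- list(data$response_names, data$response_names)
  new_csr_model(T_, lambda = lambda, B = B, data = data, pd_mode = pd_mode,
                objective = obj$value, seed = seed, mask = mask, A_hat = A)
}

stop_nonconvergence <- function(trace, reason) {
  cond <- structure(
    class = c("perturbsem_nonconvergence", "error", "condition"),
    list(message = sprintf(
      "penalized CSR fit did not converge (%s); last objective %.6g after %d iterations",
      reason, if (length(trace)) trace[length(trace)] else NA_real_,
      length(trace)),
      call = NULL, objective_trace = trace))
  stop(cond)
}

# ---- shared fitting internals ------------------------------------------

# Least-squares / lasso fit of multi-response Y on design Z.
# Returns the coefficient matrix C (ncol(Y) x ncol(Z)) with Y_i ~ C Z_i.
fit_multiresponse <- function(Z, Y, lambda, allow_minimum_norm,
                              design_label, rank_hint = NULL) {
  if (nrow(Z) < 1L) stop("at least one observation required", call. = FALSE)
  if (lambda == 0) {
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) {
      if (!allow_minimum_norm) {
        deficient <- colnames(Z)[qz$pivot[seq(qz$rank + 1L, ncol(Z))]]
        msg <- sprintf(
          "%s design matrix is rank deficient (rank %d of %d); the unpenalized fit is not unique. Offending columns: %s.",
          design_label, qz$rank, ncol(Z), paste(deficient, collapse = ", "))
        if (!is.null(rank_hint)) msg <- paste0(msg, " Note: ", rank_hint, ".")
        stop(msg, call. = FALSE)
      }
      # minimum-norm solution via pseudoinverse
      sv <- svd(Z)
      pos <- sv$d > max(dim(Z)) * .Machine$double.eps * sv$d[1]
      coefs <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) %*% Y / sv$d[pos])
      return(t(coefs))
    }
    return(t(qr.coef(qz, Y)))
  }
  t(apply(Y, 2, function(y) lasso_cd(Z, y, lambda)))
}

# Cyclic coordinate descent for min_b ||y - Z b||^2 + lambda * sum |b|.
lasso_cd <- function(Z, y, lambda, max_iter = 100000L, tol = 1e-8) {
  k <- ncol(Z)
  b <- numeric(k)
  z2 <- colSums(Z^2)
  resid <- y
  for (iter in seq_len(max_iter)) {
    delta_max <- 0
    for (j in seq_len(k)) {
      if (z2[j] == 0) next
      rho <- sum(Z[, j] * resid) + z2[j] * b[j]
      b_new <- soft_threshold(rho, lambda / 2) / z2[j]
      if (b_new != b[j]) {
        resid <- resid - Z[, j] * (b_new - b[j])
        delta_max <- max(delta_max, abs(b_new - b[j]))
        b[j] <- b_new
      }
    }
    if (delta_max < tol) break
  }
  b
}

check_b <- function(B, data) {
  B <- as_numeric_matrix(B, "B")
  p <- length(data$response_names)
  q <- length(data$drug_names)
  if (!all(dim(B) == c(p, q))) {
    stop(sprintf("B is %d x %d, expected %d responses x %d drugs",
                 nrow(B), ncol(B), p, q), call. = FALSE)
  }
  B
}

coerce_design <- function(D, q, what) {
  if (is.null(dim(D))) D <- matrix(D, nrow = 1)
  D <- as_numeric_matrix(D, what)
  if (ncol(D) != q) {
    stop(sprintf("%s has %d columns, expected %d", what, ncol(D), q),
         call. = FALSE)
  }
  D
}
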