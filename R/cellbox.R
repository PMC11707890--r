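#' Construct a linear Cellbox model
#'
#' The Cellbox ODE models response trajectories under constant perturbation
#' input `u = g(D)` as `dx_j/dt = tau_j * phi(sum_{k != j} w_jk x_k + u_j)
#' + w_jj x_j`. This module fixes the envelope `phi` to the identity and
#' `tau` to ones, giving the linear system `dx/dt = W x + u`: off-diagonal
#' `w_jk` are interaction strengths, the (negative) diagonal `w_jj` are decay
#' rates. When all eigenvalues of W have negative real part, trajectories
#' from any start converge to the steady state `-W^-1 u`; the model records
#' a `stable` flag for this regime.
#'
#' @param W p x p interaction matrix.
#' @param tau decay time-scale vector; must be all ones (the linear
#'   reduction this module implements).
#' @param envelope envelope tag; must be `"identity"`.
#' @param response_names optional response names.
#' @return An object of class `cellbox_model` with elements `W`, `tau`,
#'   `envelope`, `stable`, `response_names`.
#' @examples
#' m <- cellbox_model(W = -diag(3))
#' steady_state_closed(m, u = c(1, 2, 3))
#' @export
cellbox_model <- function(W, tau = rep(1, nrow(W)), envelope = "identity",
                          response_names = NULL) {
  W <- as_numeric_matrix(W, "W")
  p <- nrow(W)
  if (ncol(W) != p) stop("W must be square", call. = FALSE)
  if (!identical(envelope, "identity")) {
    stop("only the identity envelope is supported in the linear model",
         call. = FALSE)
  }
  if (length(tau) != p || any(tau != 1)) {
    stop("tau must be a vector of ones (linear reduction)", call. = FALSE)
  }
  response_names <- response_names %||% rownames(W) %||%
    paste0("X", seq_len(p))
  check_length(response_names, p, "response_names")
  dimnames(W) <- list(response_names, response_names)
  ev <- eigen(W, only.values = TRUE)$values
  structure(list(W = W, tau = rep(1, p), envelope = "identity",
                 stable = all(Re(ev) < 0),
                 response_names = as.character(response_names)),
            class = "cellbox_model")
}

#' @export
print.cellbox_model <- function(x, ...) {
  cat(sprintf("Linear Cellbox model: %d responses, %s\n",
              nrow(x$W),
              if (x$stable) "stable (all Re(eig W) < 0)" else "UNSTABLE"))
  invisible(x)
}

#' Right-hand side of the linear Cellbox ODE
#'
#' @param model a [cellbox_model()].
#' @param x state vector (length p).
#' @param u perturbation-input vector `g(D)` (length p).
#' @return `W x + u`, the instantaneous rate of change.
#' @export
ode_rhs <- function(model, x, u) {
  stopifnot(inherits(model, "cellbox_model"))
  p <- nrow(model$W)
  check_length(x, p, "x")
  check_length(u, p, "u")
  drop(model$W %*% x + u)
}

#' Steady state of the Cellbox ODE by numerical integration
#'
#' Integrates `dx/dt = W x + u` from `x(0) = 0` (responses are changes
#' relative to the unperturbed state) with an adaptive Runge-Kutta 4/5
#' scheme until the derivative norm `||W x + u||_inf` drops below `tol` or
#' `t_max` is reached. An unstable model triggers a warning but integration
#' is still attempted; a trajectory exceeding the overflow guard raises an
#' error (no steady state exists).
#'
#' @param model a [cellbox_model()].
#' @param u perturbation-input vector (length p).
#' @param t_max maximum integration time.
#' @param tol convergence threshold on the derivative infinity-norm.
#' @param guard overflow guard on `||x||_inf`; beyond this the trajectory is
#'   declared divergent.
#' @return A list with `x` (the state reached), `converged` (logical),
#'   `t` (time reached), `dx_norm` (final derivative norm).
#' @export
steady_state_ode <- function(model, u, t_max = 100, tol = 1e-9,
                             guard = 1e8) {
  stopifnot(inherits(model, "cellbox_model"))
  p <- nrow(model$W)
  u <- as.numeric(u)
  check_length(u, p, "u")
  if (!model$stable) {
    warning("model is not stable; steady-state convergence is not guaranteed",
            call. = FALSE)
  }
  rhs <- function(t, x, parms) list(model$W %*% x + u)
  x <- numeric(p)
  t <- 0
  chunk <- min(1, t_max)
  repeat {
    dx <- max(abs(model$W %*% x + u))
    if (dx < tol) {
      return(list(x = stats::setNames(x, model$response_names),
                  converged = TRUE, t = t, dx_norm = dx))
    }
    if (max(abs(x)) > guard) {
      stop(sprintf(
        "trajectory diverged (||x|| > %g at t = %g); no steady state", guard, t),
        call. = FALSE)
    }
    if (t >= t_max) {
      return(list(x = stats::setNames(x, model$response_names),
                  converged = FALSE, t = t, dx_norm = dx))
    }
    t_next <- min(t + chunk, t_max)
    # integrate two orders tighter than the convergence tolerance so the
    # solver's own error floor cannot stall the derivative norm above tol
    sol <- deSolve::ode(y = x, times = c(t, t_next), func = rhs,
                        parms = NULL, method = "ode45",
                        atol = tol / 100, rtol = tol / 100, maxsteps = 50000)
    if (nrow(sol) < 2 || anyNA(sol[2, -1]) || any(!is.finite(sol[2, -1]))) {
      stop(sprintf("trajectory diverged near t = %g; no steady state", t),
           call. = FALSE)
    }
    x <- as.numeric(sol[2, -1])
    t <- t_next
    chunk <- min(chunk * 2, 10)
  }
}

#' Steady state of the linear Cellbox model in closed form
#'
#' For the linear system `dx/dt = W x + u` with invertible W the unique
#' fixed point is `x* = -W^-1 u`; under stability it is the limit of every
#' trajectory.
#'
#' @param model a [cellbox_model()].
#' @param u perturbation-input vector (length p).
#' @return Named numeric vector of steady-state responses.
#' @export
steady_state_closed <- function(model, u) {
  stopifnot(inherits(model, "cellbox_model"))
  p <- nrow(model$W)
  u <- as.numeric(u)
  check_length(u, p, "u")
  if (rcond(model$W) < 1e-14) stop("W is singular", call. = FALSE)
  stats::setNames(drop(-solve(model$W, u)), model$response_names)
}

#' Fit the linear Cellbox model to perturbation data
#'
#' The steady-state objective
#' `sum_i ||X_i - (-W^-1) g(D_i)||^2 + lambda ||W - diag(W)||_1`
#' is solved exactly through the CSR reparameterization `A = W + I`: the
#' CSR fit (closed form when `lambda = 0`, proximal-gradient lasso
#' otherwise) is computed and the interaction matrix recovered as
#' `W = A_hat - I`. No ODE integration is needed — the closed-form steady
#' state makes the two objectives identical term by term, so Cellbox and
#' CSR predictions agree to machine precision.
#'
#' @param data a [perturbation_dataset()].
#' @param B p x q direct-effect matrix.
#' @param lambda nonnegative penalty weight.
#' @param mask optional p x p constraint mask (entries of W + I pinned to 0
#'   off-diagonal; see [fit_csr_penalized()]).
#' @param seed integer seed recorded with penalized fits.
#' @return A `cellbox_model` with the fitted `W`; the generating `csr_model`
#'   is attached as attribute `"csr"`.
#' @export
fit_cellbox <- function(data, B, lambda = 0, mask = NULL, seed = 0) {
  csr <- if (lambda == 0) {
    fit_csr(data, B, lambda = 0)
  } else {
    fit_csr_penalized(data, B, lambda = lambda, mask = mask, seed = seed)
  }
  if (is.null(csr$A_hat)) {
    stop("fitted total-effect matrix is singular; no Cellbox reparameterization",
         call. = FALSE)
  }
  model <- csr_to_cellbox(csr)
  attr(model, "csr") <- csr
  model
}

#' Predict steady-state responses from a fitted Cellbox model
#'
#' @param object a `cellbox_model`.
#' @param D m x q drug-concentration matrix (or length-q vector).
#' @param B p x q direct-effect matrix mapping drugs to inputs `u = B D_i`.
#' @param ... unused.
#' @return m x p matrix of predicted steady states `-W^-1 B D_i`.
#' @export
predict.cellbox_model <- function(object, D, B, ...) {
  B <- as_numeric_matrix(B, "B")
  if (nrow(B) != nrow(object$W)) {
    stop(sprintf("B has %d rows, expected %d", nrow(B), nrow(object$W)),
         call. = FALSE)
  }
  D <- coerce_design(D, ncol(B), "D")
  out <- tcrossprod(D, -solve(object$W) %*% B)
  colnames(out) <- object$response_names
  out
}

#' Convert between CSR and linear Cellbox parameterizations
#'
#' The two models are exact reparameterizations of each other:
#' `A = W + I` and `T = (I - A)^-1 = -W^-1`. `csr_to_cellbox` maps a fitted
#' CSR model to the interaction matrix `W = A_hat - I`; `cellbox_to_csr`
#' inverts the map, setting `T = -W^-1`. The round trip is the identity to
#' machine precision.
#'
#' @param csr a `csr_model` with `A_hat` present.
#' @return For `csr_to_cellbox`, a `cellbox_model`; for `cellbox_to_csr`,
#'   a `csr_model`.
#' @export
csr_to_cellbox <- function(csr) {
  stopifnot(inherits(csr, "csr_model"))
  if (is.null(csr$A_hat)) {
    stop("CSR model has no A_hat (T was singular)", call. = FALSE)
  }
  cellbox_model(W = csr$A_hat - diag(nrow(csr$A_hat)),
                response_names = csr$response_names)
}

#' @rdname csr_to_cellbox
#' @param cb a `cellbox_model`.
#' @param B optional p x q direct-effect matrix to attach for prediction.
#' @export
cellbox_to_csr <- function(cb, B = NULL) {
  stopifnot(inherits(cb, "cellbox_model"))
  p <- nrow(cb$W)
  if (rcond(cb$W) < 1e-14) stop("W is singular", call. = FALSE)
  T_ <- -solve(cb$W)
  dimnames(T_) <- list(cb$response_names, cb$response_names)
  A_hat <- cb$W + diag(p)
  dimnames(A_hat) <- dimnames(T_)
  structure(list(T = T_, A_hat = A_hat,
                 pd_report = pd_verdict(T_, "real-eigenvalue"),
                 lambda = NA_real_, B = B, objective = NULL, seed = NULL,
                 mask = NULL,
                 drug_names = if (is.null(B)) NULL else colnames(B),
                 response_names = cb$response_names),
            class = "csr_model")
}
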