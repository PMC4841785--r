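## ODE analysis of the learning dynamics: the stochastic Oja updates are
## asymptotically equivalent to dJ/dt = J Sigma - diag(J Sigma J^T) J,
## whose stable unconstrained equilibria are the principal eigenvectors.
## The non-negativity constraint is imposed by an entrywise cut-off
## applied between integration steps (projected integration).

# right-hand side; J is outputs x inputs, rows evolve independently
.ode_rhs <- function(J, Sigma) {
  G <- J %*% Sigma
  d <- rowSums(G * J)
  G - d * J
}

#' Equilibrium residual of the learning ODE
#'
#' Frobenius norm of `J Sigma - diag(J Sigma J^T) J`; zero at any
#' normalized eigenvector of `Sigma` (and at `J = 0`).
#'
#' @param J Weight matrix (outputs x inputs) or vector.
#' @param Sigma Input covariance.
#' @return Scalar residual.
#' @export
equilibrium_residual <- function(J, Sigma) {
  if (is.null(dim(J))) J <- matrix(J, nrow = 1)
  sqrt(sum(.ode_rhs(J, Sigma)^2))
}

#' Integrate the learning ODE to its equilibria
#'
#' Adaptive explicit (Heun) integration of
#' `dJ/dt = J Sigma - diag(J Sigma J^T) J`. Each row of `J` is an
#' independent output. With `constrained = TRUE` negative entries are cut
#' off (set to 0) after every accepted step; rows that collapse to zero are
#' re-initialized at random. Integration stops when the projected rate of
#' change of every row falls below `tol` (relative to the dominant
#' eigenvalue scale) or at `max_steps`.
#'
#' @param Sigma Input covariance (n x n, symmetric PSD).
#' @param n_outputs Number of independent rows to integrate.
#' @param constrained Apply the non-negativity cut-off?
#' @param J0 Optional initial matrix (rows normalized); default random
#'   uniform rows normalized to unit norm.
#' @param seed Optional seed for the random initialization.
#' @param tol Convergence tolerance on the per-row rate of change.
#' @param max_steps Step cap.
#' @return List with `J` (equilibria, rows unit-norm up to the cut-off),
#'   `residual` (per-row equilibrium residual), `converged`, `steps`,
#'   `time`.
#' @export
integrate_ode <- function(Sigma, n_outputs = 1L, constrained = FALSE,
                          J0 = NULL, seed = NULL, tol = 1e-6,
                          max_steps = 20000L) {
  n <- nrow(Sigma)
  stopifnot(ncol(Sigma) == n)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(J0)) {
    J0 <- matrix(runif(n_outputs * n), n_outputs, n)
  }
  if (is.null(dim(J0))) J0 <- matrix(J0, nrow = 1)
  J <- J0 / sqrt(rowSums(J0^2))
  lam <- .power_lambda(Sigma)
  dt <- 0.1 / lam
  t_now <- 0
  step_tol <- 0.05          # per-step local error target (relative)
  steps <- 0L
  converged <- FALSE
  project <- function(M) {
    if (constrained) {
      M[M < 0] <- 0            # the cut-off rule; no renormalization
    } else {
      # radial stabilization: the flow self-normalizes only asymptotically,
      # and the discrete map leaves an O(dt^2) radial bias; projecting back
      # to the sphere leaves the tangential dynamics (and the equilibria,
      # exactly the unit eigenvectors) unchanged
      M <- M / sqrt(rowSums(M^2))
    }
    dead <- rowSums(M^2) < 1e-12
    if (any(dead)) {
      M[dead, ] <- matrix(runif(sum(dead) * ncol(M)), sum(dead))
      M[dead, ] <- M[dead, , drop = FALSE] /
        sqrt(rowSums(M[dead, , drop = FALSE]^2))
    }
    M
  }
  while (steps < max_steps) {
    steps <- steps + 1L
    f1 <- .ode_rhs(J, Sigma)
    Je <- J + dt * f1
    f2 <- .ode_rhs(Je, Sigma)
    Jh <- J + dt * (f1 + f2) / 2
    err <- max(sqrt(rowSums((Jh - Je)^2)))
    if (err > step_tol && dt > 1e-6 / lam) {
      dt <- dt * 0.5
      next
    }
    J_new <- project(Jh)
    rate <- max(sqrt(rowSums((J_new - J)^2))) / dt
    J <- J_new
    t_now <- t_now + dt
    if (err < 0.25 * step_tol) dt <- min(dt * 1.5, 0.5 / lam)
    if (rate < tol * lam) { converged <- TRUE; break }
  }
  list(J = J, residual = apply(J, 1, equilibrium_residual, Sigma = Sigma),
       converged = converged, steps = steps, time = t_now)
}

# cheap dominant-eigenvalue estimate by power iteration
.power_lambda <- function(Sigma, iters = 30L) {
  v <- rep(1, nrow(Sigma))
  for (i in seq_len(iters)) {
    v <- as.numeric(Sigma %*% v)
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(1)
    v <- v / nv
  }
  max(sum(v * (Sigma %*% v)), .Machine$double.eps)
}
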