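## Online Hebbian learning: the single-output Oja rule and its
## multi-output hierarchical (Sanger) extension, with optional
## non-negativity rectification of the weights after every update.

#' Output activity of the network
#'
#' `psi = f(J r)`, summing the weighted presynaptic activity of the whole
#' input population through a linear or tanh activation.
#'
#' @param J Weight vector (one output) or outputs x inputs matrix.
#' @param r Input activity vector.
#' @param activation `"linear"` or `"tanh"`.
#' @return Activity, one value per output.
#' @export
output_activity <- function(J, r, activation = c("linear", "tanh")) {
  activation <- match.arg(activation)
  if (is.null(dim(J))) J <- matrix(J, nrow = 1)
  if (ncol(J) != length(r)) stop("dimension mismatch between J and r")
  v <- as.numeric(J %*% r)
  if (activation == "tanh") tanh(v) else v
}

#' One Oja update
#'
#' `J <- J + eps (psi r - psi^2 J)` with `psi = J . r`; the decay term
#' self-normalizes `||J||` towards 1, and the expected update vanishes
#' exactly at unit eigenvectors of the input covariance. With
#' `nonneg = TRUE`, entries below zero are set to zero after the update.
#'
#' @param J Weight vector.
#' @param r Input vector.
#' @param eps Learning rate (> 0).
#' @param nonneg Rectify the weights after the update?
#' @param psi Optional precomputed output activity.
#' @return Updated weight vector.
#' @export
oja_step <- function(J, r, eps, nonneg = FALSE, psi = sum(J * r)) {
  if (eps <= 0) stop("`eps` must be positive")
  if (!all(is.finite(J)) || !all(is.finite(r))) stop("non-finite inputs")
  J <- J + eps * (psi * r - psi^2 * J)
  if (nonneg) J[J < 0] <- 0
  J
}

#' One Sanger (generalized Hebbian) update
#'
#' The hierarchical multi-output rule
#' `dJ_ij = eps (r_j psi_i - psi_i sum_{k <= i} J_kj psi_k)`: output 1
#' follows the plain Oja rule, and each later output learns on data from
#' which the preceding outputs' components are subtracted
#' (Gram--Schmidt-like back-projection).
#'
#' @param J Weight matrix, outputs x inputs, rows ordered by hierarchy.
#' @param r Input vector.
#' @param eps Learning rate (> 0).
#' @param nonneg Rectify after the update?
#' @return Updated weight matrix.
#' @export
sanger_step <- function(J, r, eps, nonneg = FALSE) {
  if (eps <= 0) stop("`eps` must be positive")
  if (is.null(dim(J))) J <- matrix(J, nrow = 1)
  if (!all(is.finite(J)) || !all(is.finite(r))) stop("non-finite inputs")
  psi <- as.numeric(J %*% r)
  lower <- outer(seq_along(psi), seq_along(psi), ">=")  # k <= i mask
  back <- (lower * tcrossprod(psi)) %*% J
  J <- J + eps * (tcrossprod(psi, r) - back)
  if (nonneg) J[J < 0] <- 0
  J
}

#' Learning-rate schedule
#'
#' `eps_t = eps0 / (1 + t / t0)`: square-summable but not summable, as the
#' stochastic-approximation convergence conditions require.
#'
#' @param t Step index (0-based; vectorized).
#' @param eps0 Initial rate.
#' @param t0 Decay time constant, in steps.
#' @return Learning rate(s).
#' @export
learning_rate <- function(t, eps0 = 0.05, t0 = 1e5) {
  eps0 / (1 + t / t0)
}

#' Train a Hebbian network on an input stream
#'
#' Runs the online Oja (single output) or Sanger (multiple outputs) rule
#' over the columns of an activity matrix, with optional non-negativity
#' rectification after every step, optional temporal-derivative
#' preprocessing, and optional adaptation (running-mean subtraction of the
#' output). Weights start uniform(0, 1), normalized to unit norm. The loop
#' runs in compiled code.
#'
#' @param stream An `input_stream` or a plain cells x time matrix.
#' @param n_outputs Number of hierarchical outputs.
#' @param nonneg Constrain the weights to be non-negative?
#' @param eps0,t0 Learning-rate schedule, see [learning_rate()].
#' @param derivative Use the first temporal difference of the stream as
#'   input (zero-mean under an isotropic walk)?
#' @param adapt_delta Adaptation rate in (0, 1], or `NULL` for none.
#' @param seed Optional seed for the weight initialization.
#' @param J0 Optional initial weight matrix (overrides random init).
#' @param record_every Record diagnostics every this many steps.
#' @param tol Convergence tolerance on the windowed mean absolute weight
#'   change per entry; 0 disables early stopping.
#' @return Object of class `weight_state`: list with `J` (outputs x
#'   inputs), `norm_history`, `delta_history`, `steps`, `converged`,
#'   `diverged`.
#' @export
train <- function(stream, n_outputs = 1L, nonneg = TRUE, eps0 = 0.05,
                  t0 = 1e5, derivative = FALSE, adapt_delta = NULL,
                  seed = NULL, J0 = NULL, record_every = 1000L, tol = 0) {
  act <- if (inherits(stream, "input_stream")) stream$activity else stream
  stopifnot(is.matrix(act))
  train_lookup(act, seq_len(ncol(act)), n_outputs = n_outputs,
               nonneg = nonneg, eps0 = eps0, t0 = t0,
               derivative = derivative, adapt_delta = adapt_delta,
               seed = seed, J0 = J0, record_every = record_every, tol = tol)
}

# shared core: `lookup` holds one activity column per distinct position,
# `idx` indexes it per time step (for an explicit stream, idx = 1..T)
train_lookup <- function(lookup, idx, n_outputs = 1L, nonneg = TRUE,
                         eps0 = 0.05, t0 = 1e5, derivative = FALSE,
                         adapt_delta = NULL, seed = NULL, J0 = NULL,
                         record_every = 1000L, tol = 0) {
  n <- nrow(lookup)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(J0)) {
    J0 <- matrix(runif(n_outputs * n), n_outputs, n)
  }
  if (is.null(dim(J0))) J0 <- matrix(J0, nrow = 1)
  J0 <- J0 / sqrt(rowSums(J0^2))
  res <- train_sanger_cpp(lookup, as.integer(idx - 1L), J0,
                          eps0, t0, nonneg, derivative,
                          if (is.null(adapt_delta)) 0 else adapt_delta,
                          as.integer(record_every), tol)
  structure(
    list(J = res$J, norm_history = as.numeric(res$norm_history),
         delta_history = as.numeric(res$delta_history),
         steps = res$steps, converged = res$converged,
         diverged = res$diverged, nonneg = nonneg),
    class = "weight_state"
  )
}

#' @export
print.weight_state <- function(x, ...) {
  cat(sprintf(
    "<weight_state> %d output(s) x %d inputs, %d steps, %s%s\n",
    nrow(x$J), ncol(x$J), x$steps,
    if (x$nonneg) "non-negative" else "unconstrained",
    if (x$diverged) " [DIVERGED]" else ""))
  invisible(x)
}

#' Train a network along a trajectory
#'
#' End-to-end fast path: bins the trajectory positions on a lookup grid,
#' evaluates the ensemble's tuning curves once per grid cell, and runs the
#' compiled training loop over the per-step lookup indices. Equivalent to
#' building the full neuron-by-time stream (at the lookup resolution)
#' without materializing it.
#'
#' @param ensemble A [place_ensemble()].
#' @param traj A [generate_trajectory()] result.
#' @param lookup_res Positions-per-side of the lookup grid (default twice
#'   the cell lattice, capped at 64).
#' @param raster Optional precomputed [ensemble_raster()] at `lookup_res`.
#' @inheritParams train
#' @param ... Passed on to the training core.
#' @return A `weight_state` (see [train()]).
#' @export
train_network <- function(ensemble, traj,
                          lookup_res = min(64L,
                            2L * round(sqrt(nrow(ensemble$centers)))),
                          raster = NULL, ...) {
  if (is.null(raster)) raster <- ensemble_raster(ensemble, lookup_res)
  idx <- position_bins(traj$positions, ensemble$arena$side_length,
                       lookup_res)
  train_lookup(raster, idx, ...)
}
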