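## Batch PCA of the input covariance and the direct steady-state
## (non-negative) PCA solver on the spatial convolution objective.

#' Covariance of an input stream
#'
#' `Sigma = (1/T) sum_t (r_t - rbar)(r_t - rbar)^T` over the columns of the
#' neuron-by-time activity matrix.
#'
#' @param stream An `input_stream` (or plain matrix, cells x time) with
#'   T > 1 columns.
#' @return Symmetric n x n covariance matrix.
#' @export
covariance_from_stream <- function(stream) {
  act <- if (inherits(stream, "input_stream")) stream$activity else stream
  T <- ncol(act)
  if (is.null(T) || T <= 1L) stop("need more than one time step")
  centred <- act - rowMeans(act)
  tcrossprod(centred) / T
}

#' Occupancy-weighted spatial covariance of an ensemble
#'
#' The covariance of the binned input stream, computed from the tuning
#' rasters and an occupancy weight per pixel instead of step by step:
#' `Sigma = R W R^T - mu mu^T` with `R` the [ensemble_raster()], `W` the
#' normalized occupancy and `mu = R w`. With uniform weights this is the
#' ergodic (infinite-time) covariance; with the occupancy of a finite
#' trajectory it equals the empirical covariance of that trajectory's
#' binned stream exactly.
#'
#' @param ensemble A [place_ensemble()].
#' @param res Binning resolution.
#' @param occupancy Optional res x res count matrix (e.g. from
#'   [occupancy_map()]); default uniform.
#' @param raster Optional precomputed [ensemble_raster()] at `res`.
#' @return Symmetric n x n covariance matrix.
#' @export
covariance_from_ensemble <- function(ensemble,
                                     res = ensemble$arena$grid_resolution,
                                     occupancy = NULL, raster = NULL) {
  if (is.null(raster)) raster <- ensemble_raster(ensemble, res)
  if (is.null(occupancy)) {
    w <- rep(1 / ncol(raster), ncol(raster))
  } else {
    w <- as.numeric(occupancy) / sum(occupancy)
  }
  mu <- as.numeric(raster %*% w)
  S <- raster %*% (w * t(raster)) - tcrossprod(mu)
  (S + t(S)) / 2
}

#' Covariance of a trajectory's binned input stream
#'
#' @param ensemble A [place_ensemble()].
#' @param traj A [generate_trajectory()] result.
#' @param res Binning resolution.
#' @param raster Optional precomputed [ensemble_raster()] at `res`.
#' @return Symmetric n x n covariance matrix.
#' @export
covariance_from_trajectory <- function(ensemble, traj,
                                       res = ensemble$arena$grid_resolution,
                                       raster = NULL) {
  occ <- occupancy_map(traj, arena_config(ensemble$arena$side_length,
                                          ensemble$arena$boundary, res))
  covariance_from_ensemble(ensemble, res, occupancy = occ, raster = raster)
}

#' Top eigenpairs of a covariance matrix
#'
#' @param Sigma Symmetric matrix.
#' @param k Number of leading components to return.
#' @param tol Symmetry tolerance.
#' @return List with `values` (descending) and `vectors` (orthonormal
#'   columns).
#' @export
batch_pca <- function(Sigma, k = 1L, tol = 1e-8) {
  if (max(abs(Sigma - t(Sigma))) > tol * max(1, max(abs(Sigma)))) {
    stop("`Sigma` must be symmetric")
  }
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  k <- min(k, length(e$values))
  list(values = e$values[seq_len(k)],
       vectors = e$vectors[, seq_len(k), drop = FALSE])
}

#' Steady-state (non-negative) PCA problem
#'
#' In the limit of a dense, uniform place-cell ensemble under an ergodic
#' walk, the grid cell's activity is the spatial convolution of the weight
#' field `J(x)` with the tuning curve `r(x)`, and learning maximizes
#' `(1/|S|) int (J * r)^2` under `||J|| = 1` (and `J >= 0` when
#' constrained). The problem stores the tuning kernel rasterized on the
#' periodic arena grid, shifted to exact zero spatial sum.
#'
#' @param arena An [arena_config()] (periodic).
#' @param sigma1,sigma2 Difference-of-Gaussians widths (`sigma2 > sigma1`).
#' @param kind Tuning kind, `"dog"` or `"disk"`.
#' @param constraint `"nonneg"` or `"none"`.
#' @param inner_radius,outer_radius Disk radii when `kind = "disk"`.
#' @return Object of class `steady_state_problem` with the kernel raster,
#'   its FFT, and (initially empty) deflation components.
#' @export
steady_state_problem <- function(arena, sigma1, sigma2 = 2 * sigma1,
                                 kind = c("dog", "disk"),
                                 constraint = c("nonneg", "none"),
                                 inner_radius = sigma1,
                                 outer_radius = 2 * sigma1) {
  stopifnot(inherits(arena, "arena_config"))
  kind <- match.arg(kind)
  constraint <- match.arg(constraint)
  res <- arena$grid_resolution
  L <- arena$side_length
  # kernel centred at the origin pixel, minimum-image distances
  g <- (0:(res - 1)) * L / res
  g <- ifelse(g > L / 2, g - L, g)
  d2 <- outer(g^2, g^2, "+")
  if (kind == "dog") {
    s1 <- sum(exp(-d2 / (2 * sigma1^2)))
    s2 <- sum(exp(-d2 / (2 * sigma2^2)))
    ker <- exp(-d2 / (2 * sigma1^2)) - (s1 / s2) * exp(-d2 / (2 * sigma2^2))
  } else {
    inner <- d2 <= inner_radius^2
    ring <- d2 > inner_radius^2 & d2 <= outer_radius^2
    ker <- inner - (sum(inner) / sum(ring)) * ring
  }
  ker <- ker - mean(ker)          # exact zero spatial sum
  structure(
    list(kernel = ker, kernel_fft = fft(ker), res = res, arena = arena,
         sigma1 = sigma1, sigma2 = sigma2, kind = kind,
         constraint = constraint,
         components = list(), u_list = list()),
    class = "steady_state_problem"
  )
}

#' @export
print.steady_state_problem <- function(x, ...) {
  cat(sprintf(
    "<steady_state_problem> %s kernel, %d x %d, %s constraint, %d deflated\n",
    x$kind, x$res, x$res, x$constraint, length(x$components)))
  invisible(x)
}

# apply the (possibly deflated) kernel operator B_n to a field w
.apply_B <- function(problem, w) {
  v <- Re(fft(fft(w) * problem$kernel_fft, inverse = TRUE)) / length(w)
  for (i in seq_along(problem$components)) {
    v <- v - problem$u_list[[i]] * sum(problem$components[[i]] * w)
  }
  v
}

# apply the adjoint B_n^T
.apply_Bt <- function(problem, v) {
  w <- Re(fft(fft(v) * problem$kernel_fft, inverse = TRUE)) / length(v)
  for (i in seq_along(problem$components)) {
    w <- w - problem$components[[i]] * sum(problem$u_list[[i]] * v)
  }
  w
}

#' Steady-state objective of a weight field
#'
#' `||B J||^2` for unit-norm `J`, where `B` is the (possibly deflated)
#' convolution operator. For the undeflated periodic problem the
#' unconstrained maximum is `max_k |r_hat(k)|^2` over the discrete Fourier
#' transform of the kernel.
#'
#' @param problem A [steady_state_problem()].
#' @param J Weight field (res x res matrix or vector).
#' @return Scalar objective.
#' @export
steady_state_objective <- function(problem, J) {
  J <- matrix(J, problem$res, problem$res)
  sum(.apply_B(problem, J)^2)
}

#' Solve the steady-state problem by projected accelerated gradient
#'
#' FISTA-style ascent on the quadratic convolution objective with hard
#' constraints and no shrinkage: each step moves along the gradient
#' (computed by FFT), projects onto the non-negative orthant (if
#' constrained) and then onto the unit sphere. The step size is
#' 1/Lipschitz with the Lipschitz constant `2 max_k |r_hat(k)|^2`
#' (estimated by power iteration for deflated operators). Momentum restarts
#' whenever the objective would decrease, so the recorded objective trace
#' is non-decreasing.
#'
#' @param problem A [steady_state_problem()].
#' @param seed Optional seed for the random start.
#' @param max_iter Iteration cap.
#' @param tol Relative objective-change convergence tolerance.
#' @param J0 Optional starting field (res x res).
#' @return List with `J` (unit-norm [rate_map()]), `psi` (the convolved
#'   activity map), `objective`, `trace`, `iterations`, `converged`.
#' @export
solve_steady_state <- function(problem, seed = NULL, max_iter = 5e4,
                               tol = 1e-9, J0 = NULL) {
  res <- problem$res
  if (!is.null(seed)) set.seed(seed)
  if (is.null(J0)) {
    J <- matrix(runif(res * res), res, res)
  } else {
    J <- matrix(J0, res, res)
  }
  nonneg <- problem$constraint == "nonneg"
  proj <- function(w) {
    if (nonneg) w[w < 0] <- 0
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) w else w / nrm
  }
  J <- proj(J)
  # Lipschitz constant of the gradient
  if (length(problem$components) == 0L) {
    lam <- max(Mod(problem$kernel_fft)^2)
  } else {
    v <- J
    for (i in 1:30) {
      v <- .apply_Bt(problem, .apply_B(problem, v))
      v <- v / sqrt(sum(v^2))
    }
    lam <- sum(v * .apply_Bt(problem, .apply_B(problem, v))) * 1.2
  }
  step <- 1 / (2 * lam)
  obj <- steady_state_objective(problem, J)
  trace <- obj
  y <- J
  tk <- 1
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    grad <- 2 * .apply_Bt(problem, .apply_B(problem, y))
    J_new <- proj(y + step * grad)
    obj_new <- steady_state_objective(problem, J_new)
    if (obj_new < obj) {
      # momentum overshoot: restart from the current point
      tk <- 1
      J_new <- proj(J + step * 2 * .apply_Bt(problem, .apply_B(problem, J)))
      obj_new <- steady_state_objective(problem, J_new)
      if (obj_new < obj) { J_new <- J; obj_new <- obj }
    }
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- J_new + ((tk - 1) / tk_new) * (J_new - J)
    rel <- abs(obj_new - obj) / max(obj, .Machine$double.eps)
    J <- J_new
    if (obj_new >= obj) { obj <- obj_new; trace <- c(trace, obj) }
    tk <- tk_new
    if (rel < tol && it > 10) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("steady-state solver hit max_iter without meeting tolerance")
  }
  px <- problem$arena$side_length / res
  list(J = rate_map(J, pixel_size = px),
       psi = rate_map(matrix(.apply_B(problem, J), res, res), pixel_size = px),
       objective = obj, trace = trace, iterations = it,
       converged = converged)
}

#' Deflate a steady-state problem by a solved component
#'
#' Removes the projection of the solved unit-norm component from the
#' kernel operator (`B <- B - (B J) J^T`), so re-solving yields the next
#' 'eigenvector' in the hierarchical (Gram--Schmidt-like) sense. Deflating
#' by an exact eigenvector zeroes the reduced objective at that component.
#'
#' @param problem A [steady_state_problem()].
#' @param J A solved unit-norm component (res x res matrix or vector).
#' @return The deflated problem.
#' @export
deflate <- function(problem, J) {
  J <- matrix(J, problem$res, problem$res)
  nrm <- sqrt(sum(J^2))
  if (nrm == 0) return(problem)
  J <- J / nrm
  u <- .apply_B(problem, J)
  problem$components <- c(problem$components, list(J))
  problem$u_list <- c(problem$u_list, list(u))
  problem
}

#' Successive constrained components by deflation
#'
#' Solves the steady-state problem, deflates, and repeats. Successive
#' constrained solutions occupy new Fourier-lattice groups; once the
#' near-optimal hexagonal groups are exhausted, later components move to a
#' k-radius about sqrt(2) larger, which is the origin of the second grid
#' module.
#'
#' @param problem A [steady_state_problem()].
#' @param n_components Number of components to extract.
#' @param seed Integer seed; component i uses `seed + i`.
#' @param ... Passed to [solve_steady_state()].
#' @return List of solve results (see [solve_steady_state()]).
#' @export
solve_components <- function(problem, n_components, seed = 1, ...) {
  out <- vector("list", n_components)
  for (i in seq_len(n_components)) {
    out[[i]] <- solve_steady_state(problem, seed = seed + i, ...)
    problem <- deflate(problem, out[[i]]$J)
  }
  out
}

#' Fourier coefficient table of a weight field
#'
#' Magnitudes of the DFT of `J` on the reciprocal lattice, for inspecting
#' which k-groups a solution occupies.
#'
#' @param J res x res field.
#' @param side_length Arena side L.
#' @return Data frame `(kx, ky, radius, magnitude)` sorted by decreasing
#'   magnitude.
#' @export
fourier_table <- function(J, side_length) {
  J <- as.matrix(unclass(J))
  res <- nrow(J)
  Jf <- fft(J) / length(J)
  m <- 0:(res - 1)
  m <- ifelse(m > res / 2, m - res, m)
  k <- 2 * pi * m / side_length
  tab <- expand.grid(kx = k, ky = k)
  tab$radius <- sqrt(tab$kx^2 + tab$ky^2)
  tab$magnitude <- as.numeric(Mod(Jf))
  tab[order(-tab$magnitude), ]
}

#' Non-negative PCA of a covariance matrix
#'
#' Projected accelerated gradient (FISTA with hard constraints, no
#' shrinkage) maximizing `J^T Sigma J` over unit-norm `J`, with `J >= 0`
#' when constrained: each step follows the gradient `2 Sigma J`, clips
#' negative entries, and renormalizes. Step size 1/(2 lambda_max). This is
#' the finite-ensemble form of [solve_steady_state()]: it accepts the
#' empirical covariance of a sampled trajectory, so solution quality
#' reflects the same sampling noise the online network sees.
#'
#' @param Sigma Input covariance (symmetric PSD).
#' @param constrained Impose the non-negativity constraint?
#' @param seed Optional seed for the random uniform start.
#' @param max_iter,tol Iteration cap and relative objective tolerance.
#' @param J0 Optional start vector.
#' @return List with `J` (unit-norm vector), `objective`, `trace`,
#'   `iterations`, `converged`.
#' @export
nnpca_cov <- function(Sigma, constrained = TRUE, seed = NULL,
                      max_iter = 2e4, tol = 1e-10, J0 = NULL) {
  n <- nrow(Sigma)
  if (!is.null(seed)) set.seed(seed)
  J <- if (is.null(J0)) runif(n) else as.numeric(J0)
  proj <- function(w) {
    if (constrained) w[w < 0] <- 0
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) w else w / nrm
  }
  J <- proj(J)
  lam <- .power_lambda(Sigma)
  step <- 1 / (2 * lam)
  obj <- sum(J * (Sigma %*% J))
  trace <- obj
  y <- J; tk <- 1; converged <- FALSE; it <- 0
  while (it < max_iter) {
    it <- it + 1
    J_new <- proj(y + step * 2 * as.numeric(Sigma %*% y))
    obj_new <- sum(J_new * (Sigma %*% J_new))
    if (obj_new < obj) {
      tk <- 1
      J_new <- proj(J + step * 2 * as.numeric(Sigma %*% J))
      obj_new <- sum(J_new * (Sigma %*% J_new))
      if (obj_new < obj) { J_new <- J; obj_new <- obj }
    }
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- J_new + ((tk - 1) / tk_new) * (J_new - J)
    rel <- abs(obj_new - obj) / max(obj, .Machine$double.eps)
    J <- J_new
    if (obj_new >= obj) { obj <- obj_new; trace <- c(trace, obj) }
    tk <- tk_new
    if (rel < tol && it > 10) { converged <- TRUE; break }
  }
  list(J = J, objective = obj, trace = trace, iterations = it,
       converged = converged)
}
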