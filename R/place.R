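#' Place-cell ensemble
#'
#' A set of place-cell tuning curves tiling the arena on a square lattice
#' (by default one cell per lattice node, `n_side` per side). Three tuning
#' shapes are supported:
#'
#' * `"gaussian"` — `exp(-d^2 / (2 sigma1^2))`, peak 1 at the centre;
#' * `"dog"` — difference of Gaussians (Mexican hat),
#'   `c1 exp(-d^2/(2 sigma1^2)) - c2 exp(-d^2/(2 sigma2^2))`, with the
#'   amplitudes balanced numerically on the arena raster so each cell's
#'   discrete spatial integral is exactly zero;
#' * `"disk"` — a positive inner disk and negative outer ring, amplitudes
#'   balanced on the raster to zero integral.
#'
#' Zero-spatial-mean inputs (`dog`, `disk`) are what make the learning
#' dynamics equivalent to PCA under an ergodic walk: the temporal mean of
#' the input then vanishes without explicit centering.
#'
#' For periodic arenas all distances are minimum-image, so the tuning
#' curves wrap and the ensemble is exactly translation invariant.
#'
#' @param arena An [arena_config()].
#' @param kind Tuning shape, one of `"gaussian"`, `"dog"`, `"disk"`.
#' @param sigma1 Width of the (inner) Gaussian, arena length units.
#' @param sigma2 Width of the outer Gaussian (`dog` only); must exceed
#'   `sigma1`. Default `2 * sigma1`.
#' @param n_side Cells per side; default the arena `grid_resolution` (one
#'   cell per raster pixel).
#' @param inner_radius,outer_radius Disk radii (`disk` only); defaults
#'   `sigma1` and `2 * sigma1`.
#' @return An object of class `place_ensemble` with fields `centers`
#'   (n x 2 matrix), `kind`, widths, amplitudes and the arena.
#' @examples
#' ens <- place_ensemble(arena_config(100, grid_resolution = 25),
#'                       kind = "dog", sigma1 = 3.75)
#' ens
#' @export
place_ensemble <- function(arena, kind = c("gaussian", "dog", "disk"),
                           sigma1 = 3.75, sigma2 = 2 * sigma1,
                           n_side = arena$grid_resolution,
                           inner_radius = sigma1,
                           outer_radius = 2 * sigma1) {
  stopifnot(inherits(arena, "arena_config"))
  kind <- match.arg(kind)
  if (sigma1 <= 0) stop("`sigma1` must be positive")
  if (kind == "dog" && sigma2 <= sigma1) {
    stop("`sigma2` must exceed `sigma1` for a difference of Gaussians")
  }
  if (kind == "disk" && outer_radius <= inner_radius) {
    stop("`outer_radius` must exceed `inner_radius`")
  }
  n_side <- as.integer(n_side)
  L <- arena$side_length
  g <- (seq_len(n_side) - 0.5) * L / n_side
  centers <- as.matrix(expand.grid(x = g, y = g))

  ens <- structure(
    list(centers = centers, kind = kind, sigma1 = sigma1, sigma2 = sigma2,
         inner_radius = inner_radius, outer_radius = outer_radius,
         c1 = 1, c2 = NA_real_, arena = arena),
    class = "place_ensemble"
  )
  if (kind != "gaussian") {
    # Balance the two lobes on the arena raster so the discrete integral of
    # every cell is exactly zero (translation invariance makes one cell
    # representative of all).
    res <- arena$grid_resolution
    d2 <- .center_dist2(ens, 1L, .pixel_centers(L, res))
    if (kind == "dog") {
      s1 <- sum(exp(-d2 / (2 * sigma1^2)))
      s2 <- sum(exp(-d2 / (2 * sigma2^2)))
      ens$c2 <- s1 / s2
    } else {
      inner <- d2 <= inner_radius^2
      ring <- d2 > inner_radius^2 & d2 <= outer_radius^2
      if (!any(ring)) stop("disk outer ring covers no raster pixel")
      ens$c2 <- sum(inner) / sum(ring)
    }
  }
  ens
}

#' @export
print.place_ensemble <- function(x, ...) {
  cat(sprintf("<place_ensemble> %d %s cells, sigma1 = %g%s, arena L = %g\n",
              nrow(x$centers), x$kind, x$sigma1,
              if (x$kind == "dog") sprintf(", sigma2 = %g", x$sigma2) else "",
              x$arena$side_length))
  invisible(x)
}

# column-major pixel centre coordinates of an res x res raster over [0, L]^2
.pixel_centers <- function(L, res) {
  g <- (seq_len(res) - 0.5) * L / res
  as.matrix(expand.grid(x = g, y = g))
}

# squared distance from cell i's centre to each row of `pts`
# (minimum-image under periodic boundaries)
.center_dist2 <- function(ens, i, pts) {
  L <- ens$arena$side_length
  dx <- pts[, 1] - ens$centers[i, 1]
  dy <- pts[, 2] - ens$centers[i, 2]
  if (ens$arena$boundary == "periodic") {
    dx <- dx - L * round(dx / L)
    dy <- dy - L * round(dy / L)
  }
  dx * dx + dy * dy
}

.tuning_from_d2 <- function(ens, d2) {
  switch(ens$kind,
    gaussian = exp(-d2 / (2 * ens$sigma1^2)),
    dog = ens$c1 * exp(-d2 / (2 * ens$sigma1^2)) -
      ens$c2 * exp(-d2 / (2 * ens$sigma2^2)),
    disk = ifelse(d2 <= ens$inner_radius^2, ens$c1,
                  ifelse(d2 <= ens$outer_radius^2, -ens$c2, 0))
  )
}

#' Evaluate all tuning curves at positions
#'
#' @param ensemble A [place_ensemble()].
#' @param x Either a length-2 position or an m x 2 matrix of positions.
#' @return A vector of n cell activities (single position) or an n x m
#'   matrix (one column per position).
#' @export
eval_tuning <- function(ensemble, x) {
  stopifnot(inherits(ensemble, "place_ensemble"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  n <- nrow(ensemble$centers)
  out <- matrix(0, n, nrow(x))
  for (i in seq_len(n)) {
    out[i, ] <- .tuning_from_d2(ensemble, .center_dist2(ensemble, i, x))
  }
  if (ncol(out) == 1L) drop(out) else out
}

#' Rasterized tuning curves of an ensemble
#'
#' Evaluates every cell's tuning curve at the centres of an `res` x `res`
#' raster. This cells-by-pixels matrix is the workhorse behind spatial
#' projection of weights, lookup-table training, and occupancy-weighted
#' covariances.
#'
#' @param ensemble A [place_ensemble()].
#' @param res Raster resolution; default the arena's `grid_resolution`.
#' @return An n_cells x res^2 matrix (pixels in column-major order).
#' @export
ensemble_raster <- function(ensemble, res = ensemble$arena$grid_resolution) {
  pts <- .pixel_centers(ensemble$arena$side_length, res)
  eval_tuning(ensemble, pts)
}

#' Input activity stream along a trajectory
#'
#' The neuron-by-time matrix of place-cell activities: column t is the
#' ensemble evaluated at the agent's position at step t.
#'
#' @param ensemble A [place_ensemble()].
#' @param traj A [generate_trajectory()] result on the same arena.
#' @return An object of class `input_stream`: list with `activity`
#'   (n_cells x T), `preprocessing = "raw"` and the ensemble.
#' @export
stream_from_trajectory <- function(ensemble, traj) {
  stopifnot(inherits(traj, "trajectory"), nrow(traj$positions) >= 1)
  act <- eval_tuning(ensemble, traj$positions)
  if (is.null(dim(act))) act <- matrix(act, ncol = 1)
  structure(list(activity = act, preprocessing = "raw", ensemble = ensemble),
            class = "input_stream")
}

#' @export
print.input_stream <- function(x, ...) {
  cat(sprintf("<input_stream> %d cells x %d steps (%s)\n",
              nrow(x$activity), ncol(x$activity), x$preprocessing))
  invisible(x)
}

#' Temporal-derivative preprocessing
#'
#' Replaces the activity by its first difference in time,
#' `dr(t) = r(t+1) - r(t)`. Under an isotropic walk the expectation of the
#' difference is zero, which provides the zero-mean input PCA requires even
#' for plain Gaussian place fields.
#'
#' @param stream An `input_stream` with at least two time steps.
#' @return An `input_stream` with T - 1 columns and
#'   `preprocessing = "temporal_derivative"`.
#' @export
temporal_derivative <- function(stream) {
  stopifnot(inherits(stream, "input_stream"))
  T <- ncol(stream$activity)
  if (T < 2L) stop("temporal derivative needs at least 2 time steps")
  out <- stream
  out$activity <- stream$activity[, -1, drop = FALSE] -
    stream$activity[, -T, drop = FALSE]
  out$preprocessing <- "temporal_derivative"
  out
}

#' Adaptation (running-mean subtraction) filter
#'
#' Maintains an exponential running mean
#' `m_t = (1 - delta) m_{t-1} + delta x_t` (with `m_0 = 0`) and returns
#' `x_t - m_t`. For i.i.d. input the output mean tends to zero, so applying
#' this to the network's activation is a third route to effective zero-mean
#' input. `delta = 1` returns identically zero; `delta -> 0` returns the
#' signal unchanged.
#'
#' @param x Numeric vector, or a matrix filtered along rows.
#' @param delta Relative weight of the current sample, in (0, 1].
#' @return Filtered series, same shape as `x`.
#' @export
adaptation_filter <- function(x, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 1) {
    stop("`delta` must lie in (0, 1]")
  }
  f <- function(v) {
    m <- stats::filter(delta * v, 1 - delta, method = "recursive")
    as.numeric(v - m)
  }
  if (is.matrix(x)) t(apply(x, 1, f)) else f(x)
}

#' Signed-disk tuning parameters
#'
#' Solves the continuous zero-integral condition for a positive inner disk
#' of radius `r` and negative ring out to `R`: with inner amplitude `a`, the
#' ring amplitude is `-a r^2 / (R^2 - r^2)` so the areas weighted by
#' amplitude cancel.
#'
#' @param inner_radius,outer_radius Disk radii, `inner_radius <
#'   outer_radius`.
#' @param amplitude Inner amplitude (default 1).
#' @return List with `inner_amplitude`, `outer_amplitude` (negative), and
#'   the radii.
#' @export
make_disk <- function(inner_radius, outer_radius, amplitude = 1) {
  if (inner_radius <= 0 || outer_radius <= inner_radius) {
    stop("need 0 < inner_radius < outer_radius")
  }
  structure(list(
    inner_radius = inner_radius, outer_radius = outer_radius,
    inner_amplitude = amplitude,
    outer_amplitude = -amplitude * inner_radius^2 /
      (outer_radius^2 - inner_radius^2)
  ), class = "disk_tuning")
}

#' Project a weight vector onto place-cell space
#'
#' The spatial interpretation of a weight (or eigen-) vector `q` over the
#' ensemble: `map(x) = sum_j q_j r_j(x)`, evaluated on an `res` x `res`
#' raster. Linear in `q`.
#'
#' @param q Numeric weight vector, one entry per cell.
#' @param ensemble A [place_ensemble()].
#' @param res Raster resolution (default arena `grid_resolution`).
#' @param raster Optional precomputed [ensemble_raster()] at `res`, to
#'   amortize projection over many vectors.
#' @return A `rate_map`: an res x res matrix with attribute `pixel_size`.
#' @export
project_weights <- function(q, ensemble,
                            res = ensemble$arena$grid_resolution,
                            raster = NULL) {
  if (is.null(raster)) raster <- ensemble_raster(ensemble, res)
  stopifnot(length(q) == nrow(raster))
  m <- matrix(as.numeric(crossprod(raster, q)), res, res)
  rate_map(m, pixel_size = ensemble$arena$side_length / res)
}

#' Construct a rate map
#'
#' @param m Numeric matrix of activity over space.
#' @param pixel_size Side of one pixel in arena units.
#' @return `m` with class `rate_map` and attribute `pixel_size`.
#' @export
rate_map <- function(m, pixel_size = 1) {
  stopifnot(is.matrix(m), all(is.finite(m)))
  structure(m, pixel_size = pixel_size, class = c("rate_map", "matrix", "array"))
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> %d x %d, pixel %g, range [%.3g, %.3g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size"), min(x), max(x)))
  invisible(x)
}
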