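## Fourier-lattice theory of the steady states: tuning-curve transform,
## its peak k-dagger, PCA solution sets and degeneracy, and the
## non-negative coefficient-scan oracles for the three 2D lattice types.

#' Reciprocal k-lattice of a periodic box
#'
#' All wavevectors `k = 2 pi (m, n) / L` with integer `(m, n)` and
#' `|k| <= k_max`. Closed under negation and contains the origin.
#'
#' @param side_length Box side L.
#' @param k_max Radius cutoff in k-space.
#' @return Data frame with columns `m`, `n`, `kx`, `ky`, `radius`.
#' @export
k_lattice <- function(side_length, k_max) {
  stopifnot(side_length > 0, k_max > 0)
  mmax <- ceiling(k_max * side_length / (2 * pi))
  g <- expand.grid(m = -mmax:mmax, n = -mmax:mmax)
  kx <- 2 * pi * g$m / side_length
  ky <- 2 * pi * g$n / side_length
  r <- sqrt(kx^2 + ky^2)
  keep <- r <= k_max + 1e-12
  data.frame(m = g$m[keep], n = g$n[keep], kx = kx[keep], ky = ky[keep],
             radius = r[keep])
}

#' Fourier transform of the difference-of-Gaussians tuning curve
#'
#' Up to a positive constant, `r_hat(k) = exp(-sigma1^2 k^2 / 2) -
#' exp(-sigma2^2 k^2 / 2)`: isotropic (depends on `|k|` only), zero at the
#' origin (zero spatial mean), and vanishing at large `|k|`, with a unique
#' positive peak in between.
#'
#' @param k Wavenumber(s) `|k|` (vectorized).
#' @param sigma1,sigma2 Inner and outer widths, `sigma2 > sigma1 > 0`.
#' @return Transform values.
#' @export
r_hat <- function(k, sigma1, sigma2) {
  if (any(sigma1 <= 0) || any(sigma2 <= sigma1)) {
    stop("need sigma2 > sigma1 > 0")
  }
  exp(-0.5 * sigma1^2 * k^2) - exp(-0.5 * sigma2^2 * k^2)
}

#' Peak wavenumber of the tuning-curve transform
#'
#' The unique maximizer of [r_hat()]; in closed form
#' `k_dagger^2 = 2 log(sigma2^2 / sigma1^2) / (sigma2^2 - sigma1^2)`.
#' It sets the spatial scale of the constrained solutions: grid spacing is
#' bounded below by `4 pi / (sqrt(3) k_dagger)`. Scaling both widths by c
#' divides `k_dagger` by c.
#'
#' @inheritParams r_hat
#' @return The peak wavenumber.
#' @export
k_dagger <- function(sigma1, sigma2) {
  if (any(sigma1 <= 0) || any(sigma2 <= sigma1)) {
    stop("need sigma2 > sigma1 > 0")
  }
  sqrt(2 * log(sigma2^2 / sigma1^2) / (sigma2^2 - sigma1^2))
}

#' Hexagonal grid-spacing bound
#'
#' Spacing of a hexagonal lattice whose base wavevectors sit at radius
#' `k`: `4 pi / (sqrt(3) k)`. Since the optimal base radius can fall
#' slightly below the transform peak on a finite lattice, this is a lower
#' bound for the measured grid spacing of constrained solutions.
#'
#' @param k_dag Base radius in k-space (> 0), typically [k_dagger()].
#' @return Spacing in arena length units.
#' @export
spacing_bound <- function(k_dag) {
  if (any(k_dag <= 0)) stop("wavenumber must be positive")
  4 * pi / (sqrt(3) * k_dag)
}

#' Unconstrained PCA solutions on the k-lattice
#'
#' The lattice points maximizing the tuning transform [r_hat()]; because
#' the transform is isotropic these form full symmetry orbits of the square
#' lattice (points related by sign flips and coordinate swap), so the
#' eigenvalue degeneracy is always a multiple of 4: 8 for a generic
#' `(m, n)`, 4 when `m = 0`, `n = 0` or `|m| = |n|` (plus coincidences of
#' distinct orbits at equal radius).
#'
#' @param lattice A [k_lattice()].
#' @param sigma1,sigma2 Tuning widths passed to [r_hat()].
#' @param tol Relative tolerance for ties on the maximum.
#' @return List with `k_star` (rows of the lattice attaining the max),
#'   `degeneracy` (their count) and `radius`.
#' @export
pca_solutions <- function(lattice, sigma1, sigma2, tol = 1e-9) {
  stopifnot(nrow(lattice) > 0)
  v <- r_hat(lattice$radius, sigma1, sigma2)
  top <- max(v)
  sel <- which(v >= top - tol * max(abs(top), 1))
  list(k_star = lattice[sel, , drop = FALSE],
       degeneracy = length(sel),
       radius = lattice$radius[sel][1])
}

#' Size of a square-lattice symmetry orbit
#'
#' Number of distinct lattice points generated from `(m, n)` by sign flips
#' and coordinate swap: 8 generically, 4 if `m = 0`, `n = 0` or
#' `|m| = |n|`, 1 for the origin.
#'
#' @param m,n Integer lattice coordinates.
#' @return Orbit size.
#' @export
orbit_size <- function(m, n) {
  pts <- unique(rbind(c(m, n), c(m, -n), c(-m, n), c(-m, -n),
                      c(n, m), c(n, -m), c(-n, m), c(-n, -m)))
  nrow(pts)
}

## ---- sharply-peaked-limit coefficient scans --------------------------------
##
## In the limit of a large box and a sharply peaked transform, rescaled so
## |r_hat(k_dagger)|^2 = 1/2, the objective reduces to the summed squared
## coefficients on the base components at radius k_dagger (counting both
## signs, each weighted 1/2). Every admissible solution is a cosine series
## on the lattice generated by the base set, with a non-negative DC term
## guaranteeing J(x) >= 0, and unit total coefficient norm.

# objective of a 1D harmonic family: amplitudes a[1..M] on k, 2k, .., Mk
# (common phase; signs of a cover phase 0/pi), DC chosen minimal for
# non-negativity, everything then normalized to unit norm. Returns the
# normalized squared base coefficient a[1]^2.
.scan1d_objective <- function(a, nx = 2048) {
  x <- seq(0, 2 * pi, length.out = nx)
  M <- length(a)
  f <- 0
  for (m in seq_len(M)) f <- f + 2 * a[m] * cos(m * x)
  dc <- max(-min(f), 0)
  norm2 <- dc^2 + 2 * sum(a^2)
  a[1]^2 / norm2
}

#' 1D non-negative coefficient scan
#'
#' Maximal objective attainable by a 1D non-negative solution built from a
#' DC term plus `M` harmonics of the base frequency, in the sharply-peaked
#' limit. The search runs a coarse grid over the free harmonic amplitudes
#' (signed, which covers phases 0 and pi) followed by Nelder--Mead
#' refinement; the base amplitude is fixed to 1 by homogeneity.
#'
#' `M = 1` has the closed-form optimum 1/6 (DC = 2 x base amplitude).
#' Objectives are monotone non-decreasing in `M` and approach their ceiling
#' quickly; no 1D (or square-lattice) solution can exceed 0.25.
#'
#' @param M Number of harmonics (>= 1).
#' @param nx Spatial grid size for the non-negativity condition.
#' @return List with `objective`, `amplitudes` (unit-norm coefficients
#'   `J_1..J_M`), and `dc`.
#' @export
scan_1d <- function(M, nx = 2048) {
  M <- as.integer(M)
  if (M < 1L) stop("`M` must be at least 1")
  if (M == 1L) {
    a <- 1; obj <- .scan1d_objective(a, nx)
  } else {
    grid <- seq(-0.6, 0.6, by = 0.05)
    combos <- as.matrix(do.call(expand.grid, rep(list(grid), M - 1L)))
    best <- -Inf; besta <- NULL
    for (i in seq_len(nrow(combos))) {
      a <- c(1, combos[i, ])
      v <- .scan1d_objective(a, 512)
      if (v > best) { best <- v; besta <- a }
    }
    if (M == 2L) {
      opt <- optimize(function(p) -.scan1d_objective(c(1, p), nx),
                      c(besta[2] - 0.1, besta[2] + 0.1), tol = 1e-10)
      a <- c(1, opt$minimum)
    } else {
      opt <- optim(besta[-1], function(p) -.scan1d_objective(c(1, p), nx),
                   method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12))
      a <- c(1, opt$par)
    }
    a <- unname(a)
    obj <- unname(.scan1d_objective(a, nx))
  }
  x <- seq(0, 2 * pi, length.out = nx)
  f <- 0
  for (m in seq_len(M)) f <- f + 2 * a[m] * cos(m * x)
  dc <- max(-min(f), 0)
  nrm <- sqrt(dc^2 + 2 * sum(a^2))
  list(objective = obj, amplitudes = a / nrm, dc = dc / nrm)
}

#' Hexagonal-lattice solution and its objective
#'
#' Evaluates a non-negative solution supported on the hexagonal lattice:
#' three base wavevectors at 60-degree separations (radius 1 after
#' rescaling), their five second-order combinations, and a DC term. The
#' objective (sharply-peaked normalization) is the summed squared base
#' coefficients over both signs, `3 J1^2` for equal base amplitudes.
#'
#' The default coefficients are the best known hexagonal solution
#' (objective 0.2558, exceeding the 0.25 ceiling of square and 1D
#' lattices, which is why constrained solutions are hexagonal):
#' `J0 = 0.6449`, base `J1 = J2 = J3 = 0.292`, second harmonics
#' `J4 = J5 = J6 = -0.0101`, sums `J7 = J8 = -0.134`.
#'
#' @param dc DC coefficient `J0` (>= 0).
#' @param base Length-3 base amplitudes.
#' @param harm2 Length-3 amplitudes on the doubled base vectors.
#' @param cross Length-2 amplitudes on `k1 + k2` and `k1 + k3`.
#' @param nx Spatial grid size for the non-negativity check.
#' @return List with `objective`, `norm2` (should be 1), `min_value`
#'   (minimum of the reconstructed field), and `nonneg` flag; a field more
#'   negative than `-1e-3` triggers a warning (reported, not repaired).
#' @export
hex_objective <- function(dc = 0.6449, base = rep(0.292, 3),
                          harm2 = rep(-0.0101, 3), cross = rep(-0.134, 2),
                          nx = 256) {
  stopifnot(length(base) == 3, length(harm2) == 3, length(cross) == 2)
  b <- rbind(c(1, 0), c(-0.5, sqrt(3) / 2), c(-0.5, -sqrt(3) / 2))
  kvec <- rbind(b, 2 * b, b[1, ] + b[2, ], b[1, ] + b[3, ])
  amp <- c(base, harm2, cross)
  # field on one hexagonal unit cell (period 4*pi/sqrt(3) along y suffices;
  # use a generous square window)
  g <- seq(0, 8 * pi, length.out = nx)
  xy <- expand.grid(x = g, y = g)
  f <- rep(dc, nrow(xy))
  for (i in seq_len(8)) {
    f <- f + 2 * amp[i] * cos(kvec[i, 1] * xy$x + kvec[i, 2] * xy$y)
  }
  norm2 <- dc^2 + 2 * sum(amp^2)
  mn <- min(f)
  nonneg <- mn >= -1e-3 * max(abs(f))
  if (!nonneg) warning("reconstructed field is not non-negative")
  list(objective = sum(base^2), norm2 = norm2, min_value = mn,
       nonneg = nonneg)
}

# objective of a square-lattice coefficient set: amplitudes on (mx, my)
# with mx in 0..ord, my in -ord..ord (half-plane representatives), common
# zero phase; DC minimal for non-negativity, then unit-normalized.
.square_objective <- function(a, idx, nx = 96) {
  g <- seq(0, 2 * pi, length.out = nx)
  xy <- expand.grid(x = g, y = g)
  f <- 0
  for (i in seq_len(nrow(idx))) {
    f <- f + 2 * a[i] * cos(idx[i, 1] * xy$x + idx[i, 2] * xy$y)
  }
  dc <- max(-min(f), 0)
  norm2 <- dc^2 + 2 * sum(a^2)
  isbase <- (idx[, 1]^2 + idx[, 2]^2) == 1
  sum(a[isbase]^2) / norm2
}

#' Best non-negative solution on the square lattice
#'
#' Multi-start constrained maximization of the sharply-peaked objective
#' over truncated coefficient sets on the square lattice (base vectors
#' `(1,0)` and `(0,1)` at the optimal radius plus integer combinations up
#' to order `ord`, and a DC term). The analytic ceiling for this lattice
#' family (which includes all 1D solutions as the special case of one base
#' vector) is 0.25, strictly below the hexagonal optimum 0.2558.
#'
#' @param n_starts Number of random restarts.
#' @param ord Harmonic truncation order.
#' @param seed Optional seed for the restart draws.
#' @param nx Spatial grid size for the non-negativity condition.
#' @return List with `objective` (best found) and `amplitudes`.
#' @export
square_lattice_max <- function(n_starts = 24, ord = 2, seed = NULL,
                               nx = 96) {
  if (!is.null(seed)) set.seed(seed)
  full <- expand.grid(mx = -ord:ord, my = -ord:ord)
  full <- full[!(full$mx == 0 & full$my == 0), ]
  # one representative per +/- pair
  keep <- full$mx > 0 | (full$mx == 0 & full$my > 0)
  idx <- as.matrix(full[keep, ])
  p <- nrow(idx)
  best <- -Inf; besta <- NULL
  isbase <- (idx[, 1]^2 + idx[, 2]^2) == 1
  for (s in seq_len(n_starts)) {
    a0 <- rnorm(p, 0, 0.15)
    a0[isbase] <- abs(rnorm(sum(isbase), 0.5, 0.2))
    opt <- optim(a0, function(a) -.square_objective(a, idx, nx),
                 method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-10))
    if (-opt$value > best) { best <- -opt$value; besta <- opt$par }
  }
  # polish on a finer non-negativity grid
  opt <- optim(besta, function(a) -.square_objective(a, idx, 192),
               method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-12))
  list(objective = -opt$value, amplitudes = opt$par, index = idx)
}

#' Summary of a grid-alignment sample
#'
#' For an ensemble of solutions from random initializations, reports the
#' mean alignment and a Kolmogorov--Smirnov test against the uniform
#' distribution on \[0, 15\] degrees (the large-box prediction, with mean
#' 7.5 degrees).
#'
#' @param alignments Numeric vector of alignment angles in \[0, 15\].
#' @return List with `mean`, `ks_statistic`, `p_value`, `n`.
#' @export
alignment_distribution <- function(alignments) {
  alignments <- alignments[is.finite(alignments)]
  if (length(alignments) < 10) stop("need at least 10 alignment values")
  ks <- suppressWarnings(ks.test(alignments, "punif", 0, 15))
  list(mean = mean(alignments), ks_statistic = unname(ks$statistic),
       p_value = ks$p.value, n = length(alignments))
}
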