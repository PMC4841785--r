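#' Arena configuration
#'
#' Describes the square arena the simulated agent explores: its side length,
#' the boundary convention, and the raster resolution used for all spatial
#' fields (rate maps, tuning-curve rasters, steady-state weight fields).
#'
#' @param side_length Side of the square arena, in arbitrary length units.
#' @param boundary Either `"periodic"` (positions wrap modulo `side_length`,
#'   distances are minimum-image) or `"zero"` (walls; the walk reflects).
#' @param grid_resolution Number of raster pixels per side (>= 8).
#'
#' @return An object of class `arena_config`.
#' @examples
#' arena_config(100)
#' @export
arena_config <- function(side_length = 100, boundary = c("periodic", "zero"),
                         grid_resolution = 64L) {
  boundary <- match.arg(boundary)
  if (!is.numeric(side_length) || length(side_length) != 1L ||
      !is.finite(side_length) || side_length <= 0) {
    stop("`side_length` must be a single positive number")
  }
  grid_resolution <- as.integer(grid_resolution)
  if (grid_resolution < 8L) stop("`grid_resolution` must be at least 8")
  structure(
    list(side_length = side_length, boundary = boundary,
         grid_resolution = grid_resolution),
    class = "arena_config"
  )
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("<arena_config> L = %g, %s boundary, %d x %d raster\n",
              x$side_length, x$boundary, x$grid_resolution, x$grid_resolution))
  invisible(x)
}

#' Wrap positions into a periodic arena
#'
#' Reduces coordinates modulo the arena side so all positions lie in
#' `[0, L)`. Idempotent.
#'
#' @param x Numeric vector or matrix of coordinates.
#' @param side_length Arena side L.
#' @return Wrapped coordinates, same shape as `x`.
#' @export
wrap_position <- function(x, side_length) {
  x - side_length * floor(x / side_length)
}

# Reflect coordinates into [0, L] (zero-boundary walks). Handles overshoots
# larger than L by folding over the period 2L.
reflect_position <- function(x, side_length) {
  y <- x - 2 * side_length * floor(x / (2 * side_length))
  ifelse(y > side_length, 2 * side_length - y, y)
}

#' Simulate an isotropic random-walk trajectory
#'
#' The agent moves at constant speed; at each step its heading is the
#' previous heading plus a Gaussian increment, which makes the walk isotropic
#' (no preferred direction) and, in a periodic arena, ergodic with a uniform
#' stationary occupancy. With `boundary = "zero"` the agent reflects off the
#' walls instead of wrapping.
#'
#' @param arena An [arena_config()].
#' @param steps Number of positions to generate (>= 1).
#' @param speed Distance travelled per step (>= 0).
#' @param turn_sd Standard deviation of the per-step heading increment,
#'   radians.
#' @param seed Optional integer seed for the walk's own RNG stream; `NULL`
#'   uses the current RNG state.
#' @param start Optional starting position `c(x, y)`; default is the arena
#'   centre.
#'
#' @return An object of class `trajectory`: a list with `positions` (a
#'   `steps` x 2 matrix), `dt`, `speed`, and the `arena`.
#' @examples
#' tr <- generate_trajectory(arena_config(100), steps = 1000, seed = 1)
#' head(tr$positions)
#' @export
generate_trajectory <- function(arena, steps, speed = 1, turn_sd = 0.2,
                                seed = NULL, start = NULL) {
  stopifnot(inherits(arena, "arena_config"))
  steps <- as.integer(steps)
  if (steps < 1L) stop("`steps` must be >= 1")
  if (speed < 0) stop("`speed` must be non-negative")
  L <- arena$side_length
  if (is.null(start)) start <- c(L / 2, L / 2)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (steps == 1L || speed == 0) {
    pos <- matrix(rep(start, each = steps), ncol = 2)
  } else {
    heading <- cumsum(c(runif(1, 0, 2 * pi), rnorm(steps - 2L, 0, turn_sd)))
    dx <- speed * cos(heading)
    dy <- speed * sin(heading)
    x <- start[1] + cumsum(c(0, dx))
    y <- start[2] + cumsum(c(0, dy))
    if (arena$boundary == "periodic") {
      pos <- cbind(wrap_position(x, L), wrap_position(y, L))
    } else {
      pos <- cbind(reflect_position(x, L), reflect_position(y, L))
    }
  }
  colnames(pos) <- c("x", "y")
  structure(
    list(positions = pos, dt = 1, speed = speed, arena = arena),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d steps, speed %g, arena L = %g (%s)\n",
              nrow(x$positions), x$speed, x$arena$side_length,
              x$arena$boundary))
  invisible(x)
}

# Map positions to 1-based raster bin indices (i = column-major pixel index)
# on an `res` x `res` grid over [0, L]^2.
position_bins <- function(positions, side_length, res) {
  ix <- pmin(pmax(floor(positions[, 1] / side_length * res), 0), res - 1)
  iy <- pmin(pmax(floor(positions[, 2] / side_length * res), 0), res - 1)
  as.integer(ix + res * iy + 1)
}

#' Occupancy map of a trajectory
#'
#' Counts visits per raster pixel. The counts sum to the number of steps;
#' for a long isotropic periodic walk they converge to uniform, which is the
#' ergodicity assumption behind replacing temporal averages of the input by
#' spatial ones.
#'
#' @param traj A [generate_trajectory()] result.
#' @param arena Arena configuration; defaults to the trajectory's own.
#' @return An integer matrix `grid_resolution` x `grid_resolution` (rows = x
#'   bins, columns = y bins).
#' @export
occupancy_map <- function(traj, arena = traj$arena) {
  stopifnot(inherits(traj, "trajectory"), nrow(traj$positions) >= 1)
  res <- arena$grid_resolution
  bins <- position_bins(traj$positions, arena$side_length, res)
  counts <- tabulate(bins, nbins = res * res)
  matrix(counts, nrow = res, ncol = res)
}

#' Export / import a trajectory as delimited text
#'
#' Three whitespace-separated columns: step index, x, y.
#'
#' @param traj A trajectory.
#' @param file Path to write to / read from.
#' @param arena Arena configuration to attach on import.
#' @return `read_trajectory` returns a `trajectory`; `write_trajectory`
#'   returns `file` invisibly.
#' @export
write_trajectory <- function(traj, file) {
  df <- data.frame(t = seq_len(nrow(traj$positions)),
                   x = traj$positions[, 1], y = traj$positions[, 2])
  write.table(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file, arena) {
  df <- read.table(file, header = TRUE)
  pos <- as.matrix(df[, c("x", "y")])
  colnames(pos) <- c("x", "y")
  structure(list(positions = pos, dt = 1, speed = NA_real_, arena = arena),
            class = "trajectory")
}
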