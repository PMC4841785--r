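## Spatial analysis: autocorrelograms, gridness scores, spacing,
## orientation, and grid modules.

# full 2D cross-correlation sum S(tau) = sum_i A(i + tau) * B(i), computed
# by FFT; returns a (2R-1) x (2C-1) matrix of lag sums, lag 0 at the centre.
.xcorr2 <- function(A, B) {
  r <- nrow(A); c <- ncol(A)
  nr <- 2L * r - 1L; nc <- 2L * c - 1L
  PA <- matrix(0, nr, nc); PA[1:r, 1:c] <- A
  PB <- matrix(0, nr, nc); PB[1:r, 1:c] <- B
  out <- Re(fft(fft(PA) * Conj(fft(PB)), inverse = TRUE)) / (nr * nc)
  # row/col lags come out as 0, 1, .., r-1, -(r-1), .., -1 : recentre
  idx_r <- c((r + 1L):nr, 1L:r)
  idx_c <- c((c + 1L):nc, 1L:c)
  out[idx_r, idx_c]
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of the map with itself at every 2D lag, computed
#' over the overlapping pixels of the two shifted copies (the standard
#' construction for grid-cell analysis). The zero-lag value is exactly 1;
#' lags whose overlap contains fewer than `min_overlap` pixels, or where
#' either copy has no variance, are `NA`.
#'
#' @param map A [rate_map()] (or plain matrix; pixel size then 1).
#' @param min_overlap Minimum number of overlapping pixels for a lag to be
#'   retained.
#' @return An `autocorrelogram`: a (2R-1) x (2C-1) matrix with attributes
#'   `pixel_size` and `center` (index of the zero lag).
#' @export
autocorrelogram <- function(map, min_overlap = 20L) {
  m <- unclass(map)
  attr(m, "pixel_size") <- NULL
  if (sd(m) == 0) stop("constant map has no autocorrelogram")
  m <- (m - mean(m)) / sd(m)   # Pearson is shift/scale invariant; condition the sums
  one <- matrix(1, nrow(m), ncol(m))
  n   <- .xcorr2(one, one)
  sxy <- .xcorr2(m, m)
  sx  <- .xcorr2(m, one)   # sum of shifted copy over overlap
  sy  <- .xcorr2(one, m)   # sum of fixed copy over overlap
  sx2 <- .xcorr2(m^2, one)
  sy2 <- .xcorr2(one, m^2)
  num <- n * sxy - sx * sy
  den <- (n * sx2 - sx^2) * (n * sy2 - sy^2)
  ac <- ifelse(n >= min_overlap & den > 1e-12 * pmax(1, n)^2, # guard round-off
               num / sqrt(pmax(den, 0)), NA_real_)
  ac[!is.finite(ac)] <- NA_real_
  ctr <- c(nrow(m), ncol(m))
  ac[ctr[1], ctr[2]] <- 1
  structure(ac,
            pixel_size = if (!is.null(attr(map, "pixel_size")))
              attr(map, "pixel_size") else 1,
            center = ctr,
            class = c("autocorrelogram", "matrix", "array"))
}

#' @export
print.autocorrelogram <- function(x, ...) {
  cat(sprintf("<autocorrelogram> %d x %d lags, pixel %g\n",
              nrow(x), ncol(x), attr(x, "pixel_size")))
  invisible(x)
}

# separable Gaussian smoothing with NA-aware renormalization
.gauss_smooth <- function(m, sd = 1) {
  if (sd <= 0) return(m)
  r <- ceiling(3 * sd)
  w <- exp(-(-r:r)^2 / (2 * sd^2))
  ok <- !is.na(m)
  v <- m; v[!ok] <- 0
  sm1 <- function(x, along) {
    acc <- 0
    for (k in -r:r) {
      shifted <- .shift_mat(x, if (along == 1) k else 0,
                            if (along == 2) k else 0)
      acc <- acc + w[k + r + 1] * shifted
    }
    acc
  }
  num <- sm1(sm1(v, 1), 2)
  den <- sm1(sm1(ok + 0, 1), 2)
  out <- num / den
  out[den == 0] <- NA_real_
  out[!ok] <- NA_real_
  out
}

# shift matrix by (di, dj), padding with zeros
.shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  ri <- max(1, 1 + di):min(nr, nr + di)
  rj <- max(1, 1 + dj):min(nc, nc + dj)
  out[ri, rj] <- m[ri - di, rj - dj, drop = FALSE]
  out
}

# local maxima of the lightly smoothed autocorrelogram, returned as a data
# frame sorted by distance (pixels) from the centre
.ac_peaks <- function(ac, smooth_sd = 1) {
  s <- .gauss_smooth(unclass(ac), smooth_sd)
  s[is.na(s)] <- -Inf
  ismax <- matrix(TRUE, nrow(s), ncol(s))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & (s > .shift_mat(s, di, dj) |
                        (.shift_mat(matrix(1, nrow(s), ncol(s)), di, dj) == 0))
  }
  ismax[!is.finite(s)] <- FALSE
  idx <- which(ismax, arr.ind = TRUE)
  ctr <- attr(ac, "center")
  dx <- idx[, 1] - ctr[1]
  dy <- idx[, 2] - ctr[2]
  d <- sqrt(dx^2 + dy^2)
  ord <- order(d)
  data.frame(dx = dx[ord], dy = dy[ord], dist = d[ord],
             value = unclass(ac)[idx][ord])
}

# six off-centre peaks nearest the centre (NULL if fewer than `need`)
.six_peaks <- function(ac, need = 6L) {
  pk <- .ac_peaks(ac)
  pk <- pk[pk$dist > 1.5, , drop = FALSE]   # exclude the central peak
  if (nrow(pk) < need) return(NULL)
  pk[seq_len(6L), , drop = FALSE]
}

# bilinear interpolation of matrix values at fractional indices (xi, yj);
# NA outside the grid or when any of the four neighbours is NA
.interp_bilinear <- function(m, xi, yj) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(xi); y0 <- floor(yj)
  fx <- xi - x0; fy <- yj - y0
  ok <- x0 >= 1 & x0 + 1 <= nr & y0 >= 1 & y0 + 1 <= nc
  out <- rep(NA_real_, length(xi))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
  v00 <- m[cbind(x0, y0)];     v10 <- m[cbind(x0 + 1, y0)]
  v01 <- m[cbind(x0, y0 + 1)]; v11 <- m[cbind(x0 + 1, y0 + 1)]
  val <- (1 - fxk) * (1 - fyk) * v00 + fxk * (1 - fyk) * v10 +
    (1 - fxk) * fyk * v01 + fxk * fyk * v11
  out[ok] <- val
  out
}

#' Rotate a raster about its centre
#'
#' Bilinear interpolation; pixels mapping outside the source (or onto `NA`
#' source pixels) become `NA`.
#'
#' @param m Numeric matrix.
#' @param angle_deg Rotation angle in degrees (counter-clockwise in the
#'   x--y plane).
#' @param center Centre of rotation as fractional (row, col); default the
#'   matrix midpoint.
#' @return Rotated matrix of the same dimensions.
#' @export
rotate_raster <- function(m, angle_deg, center = (dim(m) + 1) / 2) {
  th <- angle_deg * pi / 180
  nr <- nrow(m); nc <- ncol(m)
  ij <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  x <- ij$i - center[1]; y <- ij$j - center[2]
  xs <- cos(th) * x + sin(th) * y     # inverse rotation of target coords
  ys <- -sin(th) * x + cos(th) * y
  vals <- .interp_bilinear(m, xs + center[1], ys + center[2])
  matrix(vals, nr, nc)
}

# annulus radii in pixels: from the six nearest peaks when available,
# otherwise the fixed fallback fraction of the half-width
.annulus <- function(ac) {
  pk <- .six_peaks(ac)
  half <- (min(dim(ac)) - 1) / 2
  if (is.null(pk)) {
    c(0.2 * half, 0.7 * half)
  } else {
    c(0.5 * min(pk$dist), min(1.25 * max(pk$dist), half))
  }
}

# Pearson correlation between the autocorrelogram ring and its rotations
.ring_correlations <- function(ac, angles, annulus = .annulus(ac)) {
  ctr <- attr(ac, "center")
  m <- unclass(ac)
  nr <- nrow(m); nc <- ncol(m)
  ij <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  x <- ij$i - ctr[1]; y <- ij$j - ctr[2]
  d <- sqrt(x^2 + y^2)
  ring <- d >= annulus[1] & d <= annulus[2]
  x <- x[ring]; y <- y[ring]
  v0 <- m[cbind(ij$i[ring], ij$j[ring])]
  vapply(angles, function(a) {
    th <- a * pi / 180
    xs <- cos(th) * x + sin(th) * y
    ys <- -sin(th) * x + cos(th) * y
    vr <- .interp_bilinear(m, xs + ctr[1], ys + ctr[2])
    ok <- !is.na(v0) & !is.na(vr)
    if (sum(ok) < 10 || sd(v0[ok]) == 0 || sd(vr[ok]) == 0) return(NA_real_)
    cor(v0[ok], vr[ok])
  }, numeric(1))
}

#' Hexagonal (60 degree) gridness score
#'
#' Correlates a ring of the autocorrelogram (cropped between the central
#' peak and just beyond the six surrounding maxima) with rotated copies of
#' itself and contrasts the hexagonal angles against the off-hexagonal
#' ones: `(C60 + C120)/2 - (C30 + C90 + C150)/3`. Hexagonal patterns score
#' near or above 1; isotropic patterns score near 0; square lattices score
#' negative.
#'
#' @param ac An [autocorrelogram()] (a `rate_map` is accepted and converted).
#' @return Scalar score in roughly \[-2, 2\].
#' @export
gridness60 <- function(ac) {
  ac <- .as_ac(ac)
  cg <- .ring_correlations(ac, c(30, 60, 90, 120, 150))
  mean(cg[c(2, 4)]) - mean(cg[c(1, 3, 5)])
}

#' Square (90 degree) gridness score
#'
#' `C90 - (C45 + C135)/2` on the same autocorrelogram ring as
#' [gridness60()]. Square lattices score high, hexagonal ones low.
#'
#' @inheritParams gridness60
#' @return Scalar score in roughly \[-2, 2\].
#' @export
gridness90 <- function(ac) {
  ac <- .as_ac(ac)
  cg <- .ring_correlations(ac, c(45, 90, 135))
  cg[2] - mean(cg[c(1, 3)])
}

.as_ac <- function(x) {
  if (inherits(x, "autocorrelogram")) x else autocorrelogram(x)
}

#' Grid spacing
#'
#' Median distance from the autocorrelogram centre to the six nearest
#' off-centre maxima, in arena units.
#'
#' @inheritParams gridness60
#' @return Spacing (length units), or `NA` if fewer than six peaks exist.
#' @export
grid_spacing <- function(ac) {
  ac <- .as_ac(ac)
  pk <- .six_peaks(ac)
  if (is.null(pk)) return(NA_real_)
  stats::median(pk$dist) * attr(ac, "pixel_size")
}

#' Grid orientation and alignment
#'
#' Orientation is the angle of the autocorrelogram peak closest to the
#' positive x-axis, folded into \[-30, 30) degrees (the hexagonal lattice
#' has 60-degree symmetry). Alignment is the minimal angle between the grid
#' axes and the box walls, `min(|alpha|, 30 - |alpha|)`, in \[0, 15\].
#'
#' @inheritParams gridness60
#' @return List with `orientation` (degrees) and `alignment` (degrees).
#' @export
grid_orientation <- function(ac) {
  ac <- .as_ac(ac)
  pk <- .six_peaks(ac)
  if (is.null(pk)) return(list(orientation = NA_real_, alignment = NA_real_))
  ang <- atan2(pk$dy, pk$dx) * 180 / pi
  alpha <- ang[which.min(pmin(abs(ang), abs(abs(ang) - 360)))]
  alpha <- fold_orientation(alpha)
  list(orientation = alpha, alignment = grid_alignment(alpha))
}

#' @rdname grid_orientation
#' @param alpha Orientation angle in degrees.
#' @export
fold_orientation <- function(alpha) {
  ((alpha + 30) %% 60) - 30
}

#' @rdname grid_orientation
#' @export
grid_alignment <- function(alpha) {
  a <- abs(fold_orientation(alpha))
  pmin(a, 30 - a)
}

#' All grid statistics of a rate map
#'
#' @param map A [rate_map()].
#' @return A one-row data frame: `gridness60`, `gridness90`, `spacing`,
#'   `orientation`, `alignment`.
#' @export
grid_score <- function(map) {
  ac <- autocorrelogram(map)
  ori <- grid_orientation(ac)
  data.frame(gridness60 = gridness60(ac), gridness90 = gridness90(ac),
             spacing = grid_spacing(ac), orientation = ori$orientation,
             alignment = ori$alignment)
}

#' Detect grid-spacing modules
#'
#' Splits the spacings of sufficiently grid-like outputs
#' (`gridness60 > threshold`) into two clusters by 2-means on log-spacing
#' and reports the centroid ratio. If the between-cluster gap does not
#' clearly exceed the within-cluster spread (gap test), a single module is
#' reported.
#'
#' @param spacing Numeric vector of grid spacings.
#' @param gridness Matching vector of 60-degree gridness scores (default:
#'   all qualify).
#' @param threshold Gridness threshold for inclusion.
#' @param gap_factor The between-centroid gap (log scale) must exceed
#'   `gap_factor` times the pooled within-cluster standard deviation.
#' @return List with `labels` (1 = smaller-spacing module, 2 = larger;
#'   `NA` for excluded outputs), `ratio` (larger/smaller centroid spacing,
#'   `NA` if a single module) and `single_module` flag.
#' @export
detect_modules <- function(spacing, gridness = rep(Inf, length(spacing)),
                           threshold = 0.7, gap_factor = 2) {
  stopifnot(length(spacing) == length(gridness))
  keep <- which(is.finite(spacing) & gridness > threshold)
  labels <- rep(NA_integer_, length(spacing))
  if (length(keep) < 2L) {
    return(list(labels = labels, ratio = NA_real_, single_module = TRUE))
  }
  ls <- log(spacing[keep])
  if (diff(range(ls)) < 1e-9) {
    labels[keep] <- 1L
    return(list(labels = labels, ratio = NA_real_, single_module = TRUE))
  }
  km <- suppressWarnings(kmeans(ls, centers = range(ls), iter.max = 100))
  lo <- which.min(km$centers); hi <- which.max(km$centers)
  within_sd <- sqrt(km$tot.withinss / max(1, length(ls) - 2))
  gap <- abs(diff(as.numeric(km$centers)))
  if (gap < gap_factor * within_sd || min(table(km$cluster)) < 1) {
    labels[keep] <- 1L
    return(list(labels = labels, ratio = NA_real_, single_module = TRUE))
  }
  labels[keep] <- ifelse(km$cluster == lo, 1L, 2L)
  list(labels = labels,
       ratio = exp(km$centers[hi] - km$centers[lo]),
       single_module = FALSE)
}
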