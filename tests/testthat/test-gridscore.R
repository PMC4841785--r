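test_that("autocorrelogram is a Pearson correlogram with the right symmetries", {
  m <- make_fixture("hexagonal", wavelength = 10, size = 48)
  ac <- autocorrelogram(m)
  ctr <- attr(ac, "center")
  expect_equal(ac[ctr[1], ctr[2]], 1)
  # point symmetry C(d) = C(-d)
  flipped <- ac[rev(seq_len(nrow(ac))), rev(seq_len(ncol(ac)))]
  expect_equal(unclass(ac), unclass(flipped), tolerance = 1e-6,
               ignore_attr = TRUE)
  # spot-check two lags against a brute-force Pearson correlation
  for (lag in list(c(3, 0), c(5, -4))) {
    expect_equal(ac[ctr[1] + lag[1], ctr[2] + lag[2]],
                 ac_at_lag(unclass(m), lag[1], lag[2]), tolerance = 1e-8)
  }
  expect_error(autocorrelogram(rate_map(matrix(1, 10, 10))))
})

test_that("autocorrelogram of a plane cosine is a cosine of the same wavelength", {
  size <- 64; wl <- 16
  x <- outer(seq_len(size) - 1, rep(1, size))
  m <- rate_map(cos(2 * pi * x / wl))
  ac <- autocorrelogram(m)
  ctr <- attr(ac, "center")
  lags <- -20:20
  vals <- ac[ctr[1] + lags, ctr[2]]
  expect_equal(vals, cos(2 * pi * lags / wl), tolerance = 0.05)
})

test_that("gridness scores separate hexagonal, square, striped and isotropic maps", {
  hexm <- make_fixture("hexagonal", wavelength = 14, size = 128)
  sq <- make_fixture("square", wavelength = 14, size = 128)
  st <- make_fixture("stripes", wavelength = 14, size = 128)
  achex <- autocorrelogram(hexm)
  acsq <- autocorrelogram(sq)
  expect_gt(gridness60(achex), 1)
  expect_lt(gridness90(achex), 0.2)
  expect_gt(gridness90(acsq), 0.7)
  expect_lt(gridness60(acsq), 0)
  expect_lt(abs(gridness60(autocorrelogram(st))), 0.35)

  # rotationally symmetric target pattern (concentric rings): every
  # rotation correlates equally, so both contrasts are ~ 0
  g <- seq_len(96) - 48.5
  iso <- rate_map(cos(2 * pi * sqrt(outer(g^2, g^2, "+")) / 12))
  # pixelation breaks perfect isotropy, so allow a small residual
  aciso <- autocorrelogram(iso)
  expect_lt(abs(gridness60(aciso)), 0.2)
  expect_lt(abs(gridness90(aciso)), 0.2)

  # white noise scores near zero on both
  nz <- make_fixture("noise", size = 128, seed = 4)
  acnz <- autocorrelogram(nz)
  expect_lt(abs(gridness60(acnz)), 0.3)
  expect_lt(abs(gridness90(acnz)), 0.3)
})

test_that("gridness is invariant to scaling, offsets, and 60-degree rotation", {
  hexm <- make_fixture("hexagonal", wavelength = 13, angle = 8, size = 96)
  g0 <- gridness60(autocorrelogram(hexm))
  g1 <- gridness60(autocorrelogram(rate_map(3.2 * unclass(hexm) + 7)))
  expect_equal(g0, g1, tolerance = 1e-10)
  rot <- make_fixture("hexagonal", wavelength = 13, angle = 68, size = 96)
  expect_equal(gridness60(autocorrelogram(rot)), g0, tolerance = 0.05)
})

test_that("grid spacing matches lattice geometry and scales with the map", {
  # hexagonal pattern built from cosines of wavelength wl has spacing
  # 2 wl / sqrt(3)
  wl <- 12
  hexm <- make_fixture("hexagonal", wavelength = wl, size = 128)
  sp <- grid_spacing(autocorrelogram(hexm))
  expect_equal(sp, 2 * wl / sqrt(3), tolerance = 1.5 / sp)
  hex2 <- make_fixture("hexagonal", wavelength = 2 * wl, size = 128)
  sp2 <- grid_spacing(autocorrelogram(hex2))
  expect_equal(sp2 / sp, 2, tolerance = 0.15)
})

test_that("orientation folding and alignment obey the hexagonal symmetry", {
  expect_equal(grid_alignment(0), 0)
  expect_equal(grid_alignment(15), 15)
  expect_equal(grid_alignment(25), 5)
  expect_equal(grid_alignment(-25), 5)
  expect_equal(fold_orientation(35), -25)
  expect_equal(fold_orientation(61), 1)
  a <- runif(50, -180, 180)
  expect_true(all(grid_alignment(a) >= 0 & grid_alignment(a) <= 15))
  expect_true(all(fold_orientation(a) >= -30 & fold_orientation(a) < 30))

  hexm <- make_fixture("hexagonal", wavelength = 16, angle = 10, size = 128)
  ori <- grid_orientation(autocorrelogram(hexm))
  expect_equal(abs(ori$orientation), 10, tolerance = 2.5)
})

test_that("module detection clusters spacings and applies the gap test", {
  md <- detect_modules(c(10, 10, 10, 14, 14))
  expect_false(md$single_module)
  expect_equal(md$ratio, 1.4, tolerance = 1e-8)
  expect_equal(md$labels, c(1L, 1L, 1L, 2L, 2L))

  expect_true(detect_modules(rep(10, 6))$single_module)
  # low-gridness outputs are excluded
  md2 <- detect_modules(c(10, 10, 14, 14, 99), gridness = c(1, 1, 1, 1, 0.1))
  expect_true(is.na(md2$labels[5]))
  expect_equal(md2$ratio, 1.4, tolerance = 1e-8)
})
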