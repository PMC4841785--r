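test_that("gaussian tuning peaks at 1 on its centre and wraps periodically", {
  ens <- place_ensemble(small_arena(), kind = "gaussian", sigma1 = 5,
                        n_side = 8)
  for (i in c(1L, 30L, 64L)) {
    v <- eval_tuning(ens, ens$centers[i, ])
    expect_equal(v[i], 1)
    expect_true(all(v > 0 & v <= 1))
  }
  # translation invariance under periodic boundaries: shifting the query by
  # a lattice period reproduces the same activity vector
  x <- c(12.3, 47.1)
  expect_equal(eval_tuning(ens, x),
               eval_tuning(ens, x + c(100, 0)), tolerance = 1e-12)
})

test_that("dog and disk rasters have zero discrete integral", {
  for (kind in c("dog", "disk")) {
    ens <- place_ensemble(small_arena(), kind = kind, sigma1 = 4,
                          n_side = 8)
    R <- ensemble_raster(ens)
    rel <- abs(rowSums(R)) / rowSums(abs(R))
    expect_lt(max(rel), 1e-6)
  }
  expect_error(place_ensemble(small_arena(), kind = "dog", sigma1 = 4,
                              sigma2 = 4))
})

test_that("dog amplitude balance matches the large-arena analytic ratio", {
  # in 2D the zero-integral condition gives c1/c2 = (sigma2/sigma1)^2
  ens <- place_ensemble(arena_config(200, grid_resolution = 64),
                        kind = "dog", sigma1 = 3, sigma2 = 6, n_side = 8)
  expect_equal(ens$c1 / ens$c2, (6 / 3)^2, tolerance = 1e-3)
})

test_that("disk amplitudes solve the zero-integral condition analytically", {
  d <- make_disk(2, 4, amplitude = 1)
  expect_equal(d$outer_amplitude, -4 / (16 - 4))
  # equal areas with amplitudes (+1, -1): r^2 = R^2 - r^2
  d2 <- make_disk(1, sqrt(2))
  expect_equal(d2$outer_amplitude, -1, tolerance = 1e-12)
  expect_error(make_disk(3, 2))
  # value at the centre equals the inner amplitude
  ens <- place_ensemble(small_arena(), kind = "disk", sigma1 = 5,
                        n_side = 8)
  v <- eval_tuning(ens, ens$centers[1, ])
  expect_equal(v[1], ens$c1)
})

test_that("input streams follow the trajectory", {
  ens <- place_ensemble(small_arena(), kind = "gaussian", sigma1 = 5,
                        n_side = 8)
  ar <- ens$arena
  tr1 <- generate_trajectory(ar, steps = 1, seed = 1)
  s1 <- stream_from_trajectory(ens, tr1)
  expect_equal(dim(s1$activity), c(64L, 1L))

  # stationary agent on a cell centre: that cell's row is constant 1
  tr0 <- generate_trajectory(ar, steps = 5, speed = 0, seed = 1,
                             start = ens$centers[10, ])
  s0 <- stream_from_trajectory(ens, tr0)
  expect_equal(unname(s0$activity[10, ]), rep(1, 5))

  # column t equals direct tuning evaluation at X(t)
  tr <- generate_trajectory(ar, steps = 7, seed = 2)
  s <- stream_from_trajectory(ens, tr)
  expect_equal(s$activity[, 4], eval_tuning(ens, tr$positions[4, ]))
})

test_that("temporal derivative is zero-mean on isotropic walks", {
  ens <- place_ensemble(small_arena(), kind = "gaussian", sigma1 = 8,
                        n_side = 8)
  tr <- generate_trajectory(ens$arena, steps = 3, speed = 0, seed = 1)
  s <- stream_from_trajectory(ens, tr)
  d <- temporal_derivative(s)
  expect_equal(ncol(d$activity), 2L)
  expect_true(all(d$activity == 0))
  expect_error(temporal_derivative(
    stream_from_trajectory(ens, generate_trajectory(ens$arena, 1, seed = 1))))

  tr2 <- generate_trajectory(ens$arena, steps = 2e4, seed = 5)
  d2 <- temporal_derivative(stream_from_trajectory(ens, tr2))
  mu <- rowMeans(d2$activity)
  se <- apply(d2$activity, 1, sd) / sqrt(ncol(d2$activity))
  expect_true(all(abs(mu) < 4 * se + 1e-12))
})

test_that("dog inputs have near-zero temporal mean under a uniform walk", {
  ens <- small_dog_ensemble(n_side = 8)
  tr <- generate_trajectory(ens$arena, steps = 3e4, seed = 11)
  s <- stream_from_trajectory(ens, tr)
  mu <- rowMeans(s$activity)
  sdv <- apply(s$activity, 1, sd)
  expect_lt(max(abs(mu) / sdv), 0.15)
})

test_that("adaptation filter limits behave as designed", {
  x <- runif(200)
  expect_equal(adaptation_filter(x, 1), rep(0, 200))
  expect_equal(adaptation_filter(x, 1e-9), x, tolerance = 1e-5)
  expect_error(adaptation_filter(x, 0))
  expect_error(adaptation_filter(x, 1.5))

  set.seed(3)
  y <- runif(1e5)
  out <- adaptation_filter(y, 0.01)
  se <- sd(y) / sqrt(length(y))
  expect_lt(abs(mean(out)), 5 * se)
})

test_that("uniformly tiled periodic ensemble has a circulant covariance", {
  ens <- small_dog_ensemble(res = 16L, n_side = 8L)
  Sigma <- covariance_from_ensemble(ens, res = 16)
  n <- nrow(Sigma)
  # every row is a permutation (cyclic in the 2D cell index) of row 1
  for (i in c(2L, 17L, 40L)) {
    expect_equal(sort(Sigma[i, ]), sort(Sigma[1, ]), tolerance = 1e-8)
  }
  # and eigenvectors are sinusoids: the top eigenvector's DFT power is
  # confined to a single k-radius shell of the 8 x 8 cell lattice
  e <- batch_pca(Sigma, 1)
  q <- matrix(e$vectors[, 1], 8, 8)
  power <- Mod(fft(q))^2 / sum(Mod(fft(q))^2)
  m <- ifelse(0:7 > 4, 0:7 - 8, 0:7)
  rad2 <- outer(m^2, m^2, "+")
  dom <- rad2[which.max(power)]
  expect_gt(sum(power[rad2 == dom]), 0.99)
})
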