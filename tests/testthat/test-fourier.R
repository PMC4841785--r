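test_that("k-lattice is symmetric and contains the origin", {
  lat <- k_lattice(100, 0.5)
  expect_true(any(lat$m == 0 & lat$n == 0))
  # closed under negation
  key <- paste(lat$m, lat$n)
  expect_true(all(paste(-lat$m, -lat$n) %in% key))
  expect_true(all(lat$radius <= 0.5 + 1e-9))
})

test_that("tuning transform vanishes at 0 and infinity and peaks at k_dagger", {
  expect_equal(r_hat(0, 3.75, 7.5), 0)
  expect_lt(r_hat(100, 3.75, 7.5), 1e-12)
  expect_error(r_hat(1, 5, 3))

  kd <- k_dagger(3.75, 7.5)
  expect_equal(kd, sqrt(2 * log(4) / (7.5^2 - 3.75^2)), tolerance = 1e-12)
  # brute-force grid maximizer agrees with the closed form
  kk <- seq(1e-4, 1, length.out = 2e5)
  expect_equal(kk[which.max(r_hat(kk, 3.75, 7.5))], kd, tolerance = 1e-5)
  # scaling both widths by c divides the peak by c
  expect_equal(k_dagger(2 * 3.75, 2 * 7.5), kd / 2, tolerance = 1e-12)
})

test_that("rasterized dog kernel transform is proportional to the closed form", {
  ar <- arena_config(100, grid_resolution = 64)
  p <- steady_state_problem(ar, 3.75, 7.5)
  num <- Re(p$kernel_fft)
  m <- ifelse(0:63 > 32, 0:63 - 64, 0:63)
  k <- 2 * pi * m / 100
  kr <- sqrt(outer(k^2, k^2, "+"))
  ana <- r_hat(pmax(kr, 1e-12), 3.75, 7.5)
  keep <- kr > 0 & kr < 1.5
  expect_gt(cor(num[keep], ana[keep]), 0.999)
})

test_that("PCA solution degeneracy is always a multiple of 4", {
  lat <- k_lattice(100, 1)
  # exhaustively: every radius shell on the lattice has size divisible by 4
  shells <- table(round(lat$radius[lat$radius > 0], 9))
  expect_true(all(shells %% 4 == 0))
  expect_equal(orbit_size(4, 1), 8)
  expect_equal(orbit_size(4, 0), 4)
  expect_equal(orbit_size(3, 3), 4)
  sol <- pca_solutions(lat, 3.75, 7.5)
  expect_equal(sol$degeneracy %% 4, 0)
})

test_that("1D coefficient scan reproduces the analytic table", {
  s1 <- scan_1d(1, nx = 4096)
  expect_equal(s1$objective, 1 / 6, tolerance = 1e-5)
  # M = 1 optimum: DC = 2 x base amplitude
  expect_equal(s1$dc, 2 * s1$amplitudes[1], tolerance = 1e-6)
  expect_equal(6 * s1$amplitudes[1]^2, 1, tolerance = 1e-5)

  s2 <- scan_1d(2)
  s3 <- scan_1d(3)
  expect_equal(s2$objective, 0.2367, tolerance = 2e-3)
  expect_equal(s3$objective, 0.2457, tolerance = 2e-3)
  # monotone in M, rapidly saturating, never above the lattice bound
  s4 <- scan_1d(4)
  expect_true(all(diff(c(s1$objective, s2$objective, s3$objective,
                         s4$objective)) >= -1e-9))
  expect_lt(s4$objective - s3$objective, 1e-3)
  expect_lt(s4$objective, 0.25)
})

test_that("hexagonal solution: objective, norm, and non-negativity", {
  h <- hex_objective()
  expect_equal(h$objective, 0.2558, tolerance = 2e-4)
  expect_equal(h$norm2, 1, tolerance = 5e-4)
  expect_true(h$nonneg)
  # DC-only solution has zero objective
  h0 <- hex_objective(dc = 1, base = rep(0, 3), harm2 = rep(0, 3),
                      cross = rep(0, 2))
  expect_equal(h0$objective, 0)
  expect_warning(hex_objective(dc = 0, base = rep(0.5, 3),
                               harm2 = rep(0, 3), cross = rep(0, 2)))
})

test_that("square-lattice maximum stays below the 0.25 bound and above 1D", {
  sq <- square_lattice_max(n_starts = 12, seed = 5)
  expect_lte(sq$objective, 0.25 + 1e-3)
  # it should at least recover the best 1D solution, a special case
  expect_gt(sq$objective, 0.23)
  # hexagonal solution beats every square/1D one
  expect_gt(hex_objective()$objective, sq$objective)
})

test_that("spacing bound is inversely proportional to the base radius", {
  kd <- k_dagger(3.75, 7.5)
  expect_equal(spacing_bound(kd), 4 * pi / (sqrt(3) * kd))
  expect_equal(spacing_bound(2 * kd), spacing_bound(kd) / 2)
  expect_equal(spacing_bound(kd), 28.3, tolerance = 0.01)
  expect_error(spacing_bound(0))
})

test_that("alignment summary recovers uniform and degenerate samples", {
  set.seed(8)
  u <- runif(400, 0, 15)
  s <- alignment_distribution(u)
  expect_equal(s$mean, 7.5, tolerance = 0.75)
  expect_gt(s$p_value, 0.01)
  s2 <- alignment_distribution(rep(7.5, 50))
  expect_lt(s2$p_value, 1e-6)
  expect_error(alignment_distribution(1:5))
})
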