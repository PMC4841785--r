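test_that("stream covariance: constant, rank-2, and error cases", {
  expect_equal(covariance_from_stream(matrix(3, 4, 10)),
               matrix(0, 4, 4))
  # two orthogonal alternating patterns give a rank-2 covariance
  a <- c(1, -1, 0, 0); b <- c(0, 0, 1, -1)
  X <- cbind(a, b, -a, -b, a, b, -a, -b)
  S <- covariance_from_stream(X)
  expect_equal(sum(eigen(S, symmetric = TRUE)$values > 1e-10), 2)
  expect_error(covariance_from_stream(matrix(1, 3, 1)))
  expect_error(batch_pca(matrix(c(1, 2, 3, 4), 2)))
})

test_that("trajectory covariance equals the binned stream covariance", {
  ens <- small_dog_ensemble(res = 16L, n_side = 8L)
  tr <- generate_trajectory(ens$arena, steps = 400, seed = 3)
  S1 <- covariance_from_trajectory(ens, tr, res = 16)
  # oracle: build the stream explicitly at the binned positions
  res <- 16; L <- 100
  bin_centre <- function(p) (floor(p / L * res) + 0.5) * L / res
  pos <- apply(tr$positions, 2, bin_centre)
  S2 <- covariance_from_stream(eval_tuning(ens, pos))
  expect_equal(S1, S2, tolerance = 1e-8)
})

test_that("unconstrained steady-state solver attains the Fourier optimum", {
  ar <- arena_config(100, grid_resolution = 32)
  p <- steady_state_problem(ar, 3.75, 7.5, constraint = "none")
  s <- solve_steady_state(p, seed = 4)
  opt <- max(Mod(p$kernel_fft)^2)
  expect_equal(s$objective, opt, tolerance = 1e-6)
  expect_true(all(diff(s$trace) >= 0))
  # the solution is a pure cosine: all DFT power on one k-shell
  tab <- fourier_table(s$J, 100)
  dom <- tab$radius[1]
  shell <- abs(tab$radius - dom) < 1e-9
  expect_gt(sum(tab$magnitude[shell]^2) / sum(tab$magnitude^2), 1 - 1e-5)
})

test_that("constrained solutions are feasible and weaker than unconstrained", {
  ar <- arena_config(100, grid_resolution = 32)
  pc <- steady_state_problem(ar, 3.75, 7.5, constraint = "nonneg")
  pu <- steady_state_problem(ar, 3.75, 7.5, constraint = "none")
  sc <- solve_steady_state(pc, seed = 5)
  su <- solve_steady_state(pu, seed = 5)
  expect_gte(min(sc$J), 0)
  expect_equal(sum(sc$J^2), 1, tolerance = 1e-8)
  expect_lte(sc$objective, su$objective)
})

test_that("Parseval: spatial objective equals the Fourier-domain sum", {
  ar <- arena_config(100, grid_resolution = 32)
  p <- steady_state_problem(ar, 3.75, 7.5)
  set.seed(6)
  J <- matrix(runif(32 * 32), 32)
  J <- J / sqrt(sum(J^2))
  spatial <- steady_state_objective(p, J)
  fourier <- sum(Mod(fft(J) * p$kernel_fft)^2) / (32 * 32)
  expect_equal(spatial, fourier, tolerance = 1e-6)
  # norm identity too
  expect_equal(sum(J^2), sum(Mod(fft(J))^2) / (32 * 32), tolerance = 1e-8)
})

test_that("unconstrained solver agrees with batch PCA of the circulant operator", {
  ar <- arena_config(60, grid_resolution = 12)
  p <- steady_state_problem(ar, 4, 8, constraint = "none")
  s <- solve_steady_state(p, seed = 7)
  # explicit matrix of the operator A = B^T B on the 144-pixel space
  P <- 12 * 12
  A <- matrix(0, P, P)
  for (j in seq_len(P)) {
    e <- matrix(0, 12, 12); e[j] <- 1
    A[, j] <- as.numeric(gridpca:::.apply_Bt(p, gridpca:::.apply_B(p, e)))
  }
  lam1 <- batch_pca((A + t(A)) / 2, 1)$values[1]
  expect_equal(s$objective, lam1, tolerance = 1e-6 * lam1)
})

test_that("deflation removes a solved component and preserves others", {
  ar <- arena_config(60, grid_resolution = 16)
  p <- steady_state_problem(ar, 4, 8, constraint = "none")
  s <- solve_steady_state(p, seed = 8)
  pd <- deflate(p, s$J)
  # reduced objective at the removed component is ~ 0
  expect_lt(steady_state_objective(pd, s$J), 1e-8 * s$objective)
  # deflating by the zero field changes nothing
  p0 <- deflate(p, matrix(0, 16, 16))
  expect_equal(length(p0$components), 0L)
  expect_equal(steady_state_objective(p0, s$J), s$objective)
})

test_that("matrix-form nnpca matches the eigen solution when unconstrained", {
  set.seed(9)
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  S <- Q %*% diag(c(5, 3, 2, 1, 0.5, 0.1)) %*% t(Q)
  sol <- nnpca_cov(S, constrained = FALSE, seed = 2)
  expect_equal(sol$objective, 5, tolerance = 1e-6)
  q1 <- batch_pca(S, 1)$vectors[, 1]
  expect_gt(abs(sum(sol$J * q1)), 1 - 1e-5)
  # constrained solutions are feasible with a weaker objective
  solc <- nnpca_cov(S, constrained = TRUE, seed = 2)
  expect_gte(min(solc$J), 0)
  expect_equal(sum(solc$J^2), 1, tolerance = 1e-10)
  expect_lte(solc$objective, sol$objective + 1e-12)
})

test_that("restart robustness: constrained solutions are hexagonal across seeds", {
  ar <- arena_config(100, grid_resolution = 48)
  p <- steady_state_problem(ar, 3.75, 7.5, constraint = "nonneg")
  g <- sapply(1:10, function(s) {
    gridness60(autocorrelogram(solve_steady_state(p, seed = s)$psi))
  })
  expect_gt(median(g), 0.7)
})
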