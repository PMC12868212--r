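test_that("analytic spectra and the constant null vector are recovered", {
  b <- spectral_basis(build_laplacian(graph_snapshot(path3_adjacency())), 3)
  expect_equal(b$values, c(0, 1, 3), tolerance = 1e-10)
  b4 <- spectral_basis(build_laplacian(graph_snapshot(complete_adjacency(4))), 4)
  expect_equal(b4$values, c(0, 4, 4, 4), tolerance = 1e-10)
  # connected graph: lambda_1 = 0 with constant eigenvector
  snap <- random_snapshot(15, p = 0.4, seed = 2)
  b1 <- spectral_basis(build_laplacian(snap), 3)
  expect_equal(b1$values[1], 0, tolerance = 1e-10)
  expect_equal(stats::sd(b1$vectors[, 1]), 0, tolerance = 1e-8)
})

test_that("the basis is orthonormal with ascending eigenvalues and fixed signs", {
  snap <- random_snapshot(30, p = 0.2, seed = 5)
  b <- spectral_basis(build_laplacian(snap), 10)
  expect_lt(max(abs(crossprod(b$vectors) - diag(10))), 1e-8)
  expect_true(all(diff(b$values) >= -1e-12))
  for (k in 1:10) expect_gt(b$vectors[which.max(abs(b$vectors[, k])), k], 0)
})

test_that("non-symmetric input is rejected", {
  M <- matrix(rnorm(16), 4)
  expect_error(spectral_basis(M, 2), "symmetric")
})

test_that("dense and Lanczos eigensolvers agree on a 200-node graph", {
  g <- generate_dynamic_sbm(sbm_config(n = 200, k = 4, p_in = 0.2, p_out = 0.02,
                                       n_snapshots = 1, rewire = 0, seed = 9))
  L <- build_laplacian(snapshot(g, 0))
  bd <- spectral_basis(L, 12, method = "dense")
  bi <- spectral_basis(L, 12, method = "iterative", seed = 4)
  expect_equal(bd$values, bi$values, tolerance = 1e-6)
  # eigenvectors agree up to the (fixed) sign convention
  for (k in c(1, 2, 5, 12)) {
    expect_lt(min(sum((bd$vectors[, k] - bi$vectors[, k])^2),
                  sum((bd$vectors[, k] + bi$vectors[, k])^2)), 1e-8)
  }
})

test_that("identity filter is an exact round trip", {
  snap <- random_snapshot(20, p = 0.3, seed = 7)
  b <- spectral_basis(build_laplacian(snap), 20)
  X <- matrix(rnorm(20 * 4), 20)
  kern <- filter_kernel("polynomial", coefficients = 1)   # phi == 1
  expect_equal(apply_spectral_filter(X, b, kern, passthrough = FALSE), X,
               tolerance = 1e-8)
})

test_that("keeping only the constant mode collapses columns to their means", {
  snap <- random_snapshot(18, p = 0.5, seed = 8)   # connected
  b <- spectral_basis(build_laplacian(snap), 6)
  X <- matrix(rnorm(18 * 3), 18)
  kern <- filter_kernel("cutoff", cutoff = 1)
  Xf <- apply_spectral_filter(X, b, kern, passthrough = FALSE)
  for (j in 1:3) expect_equal(Xf[, j], rep(mean(X[, j]), 18), tolerance = 1e-8)
  # exponential kernel in the tau -> infinity limit does the same
  Xe <- apply_spectral_filter(X, b, filter_kernel("exponential", tau = 1e6),
                              passthrough = FALSE)
  expect_equal(Xe, Xf, tolerance = 1e-7)
})

test_that("filtering is non-expansive and projection obeys Parseval", {
  snap <- random_snapshot(25, p = 0.25, seed = 3)
  X <- matrix(rnorm(25 * 5), 25)
  for (r in c(5, 15, 25)) {
    b <- spectral_basis(build_laplacian(snap), r)
    expect_lte(norm(crossprod(b$vectors, X), "F"), norm(X, "F") + 1e-10)
    Xf <- apply_spectral_filter(X, b, filter_kernel("exponential", tau = 0.7),
                                passthrough = FALSE)
    expect_lte(norm(Xf, "F"), norm(X, "F") + 1e-10)
  }
  # full-rank reconstruction is exact
  bfull <- spectral_basis(build_laplacian(snap), 25)
  expect_equal(bfull$vectors %*% crossprod(bfull$vectors, X), X, tolerance = 1e-8)
})

test_that("kernels outside [0, 1] are rejected", {
  snap <- random_snapshot(10, p = 0.4, seed = 1)
  b <- spectral_basis(build_laplacian(snap), 5)
  X <- matrix(rnorm(10 * 2), 10)
  bad <- filter_kernel("polynomial", coefficients = c(0.5, 1))  # exceeds 1
  expect_error(apply_spectral_filter(X, b, bad), "\\[0, 1\\]")
})

test_that("hallucination indices follow the direct arithmetic", {
  eta <- hallucination_indices(c(0, 1, 2, 5), F = 0.2, leakage = 0.3)
  expect_equal(eta$eta, c(-0.3, -0.1, 0.1, 0.7))
  expect_equal(which(eta$unstable), c(3L, 4L))
  expect_equal(eta_max(eta), 0.7)
  # the constant mode is always stable
  expect_lt(eta$eta[1], 0)
  expect_error(hallucination_indices(c(0, 1), F = -1, leakage = 0.3), "F")
  expect_error(hallucination_indices(c(0, 1), F = 1, leakage = c(1, 2, 3)), "length")
})

test_that("eta is increasing in lambda and the unstable set grows with F", {
  lam <- sort(runif(20, 0, 6))
  prev_unstable <- 0
  for (Fg in c(0.05, 0.1, 0.2, 0.4)) {
    eta <- hallucination_indices(lam, F = Fg, leakage = 0.3)
    expect_true(all(diff(eta$eta) >= 0))
    expect_gte(sum(eta$unstable), prev_unstable)
    prev_unstable <- sum(eta$unstable)
  }
})

test_that("mode leakage is the Rayleigh quotient of a diagonal leakage", {
  snap <- random_snapshot(12, p = 0.4, seed = 6)
  b <- spectral_basis(build_laplacian(snap), 4)
  cvec <- runif(12, 0.2, 0.8)
  ck <- mode_leakage(b, cvec)
  manual <- sapply(1:4, function(k) sum(b$vectors[, k]^2 * cvec))
  expect_equal(ck, manual)
  expect_equal(mode_leakage(b, 0.3), rep(0.3, 4))
})
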