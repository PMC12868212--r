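test_that("scalar and identity Lyapunov solves match hand algebra", {
  expect_equal(solve_lyapunov_P(C = 1, W = 0), matrix(1, 1, 1), ignore_attr = TRUE)
  expect_equal(solve_lyapunov_P(C = diag(2), W = 0), diag(2), tolerance = 1e-12)
})

test_that("Lyapunov residual is tiny and P is PD on random Hurwitz systems", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(2:50, 1)
    # random Hurwitz A: negative-definite symmetric part plus skew noise
    R <- matrix(rnorm(n * n, sd = 0.5), n)
    A <- -(crossprod(R) / n + diag(runif(n, 0.3, 1))) +
      (R - t(R)) * 0.1
    P <- solve_lyapunov_P(A = A)
    expect_lt(norm(t(A) %*% P + P %*% A + 2 * diag(n), "F"), 1e-8)
    expect_gt(min(eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("non-Hurwitz systems are refused with the offending eigenvalue", {
  expect_error(solve_lyapunov_P(C = 0.1, W = matrix(1), F = 1), "Hurwitz")
  expect_error(solve_lyapunov_P(A = matrix(c(0.2, 0, 0, -1), 2)), "Hurwitz")
})

test_that("stability margin reproduces the worked examples", {
  expect_equal(stability_margin(diag(3), C = 0.7 * diag(3), W = 0), 0.7)
  expect_equal(stability_margin(diag(2), C = diag(c(1, 2)), W = diag(2), F = 0.5), 0.5)
  expect_equal(stability_margin(diag(2), C = 0.1 * diag(2), W = diag(2), F = 1), -0.9)
})

test_that("commuting-case closed form equals the P = I margin", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    Ahat <- matrix(rnorm(n * n), n); Ahat <- (Ahat + t(Ahat)) / 2
    c0 <- runif(1, 0.5, 2); s <- runif(1, -0.5, 0.5); Fg <- runif(1, 0.2, 1.5)
    mu <- eigen(Ahat, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(stability_margin(diag(n), C = c0 * diag(n), W = s * Ahat, F = Fg),
                 stability_margin_proxy(c0, s, mu, F = Fg), tolerance = 1e-8)
  }
})

test_that("the verified condition is consistent with the computed margin", {
  expect_true(verify_stability_condition(diag(2), diag(2), W = 0, rho = 1.5)$holds)
  expect_equal(verify_stability_condition(diag(2), diag(2), W = 0, rho = 1.5)$slack, 0.5)
  expect_false(verify_stability_condition(diag(2), diag(2), W = 0, rho = 2.5)$holds)
  expect_true(verify_stability_condition(diag(3), diag(c(1, 2, 3)), W = 0, rho = 0)$holds)
  # margin from the solver-backed P always satisfies its own condition
  set.seed(21)
  for (i in 1:8) {
    n <- sample(3:15, 1)
    W <- matrix(rnorm(n * n, sd = 0.1), n); W <- (W + t(W)) / 2
    C <- diag(runif(n, 0.8, 1.5))
    P <- solve_lyapunov_P(C, W, F = 1)
    rho <- stability_margin(P, C, W, F = 1)
    if (rho >= 0) {
      expect_true(verify_stability_condition(P, C, W, F = 1,
                                             rho = max(rho - 1e-9, 0))$holds)
    }
  }
})

test_that("error bound evaluates its closed-form special cases", {
  P <- diag(2)
  expect_equal(error_bound(1.5, rho = 0.5, P, u_bar = 0.2, alpha = 0.7, t = 0),
               1.5 + 1 * 0.2 / 0.5)
  ts <- c(0.5, 1, 3)
  expect_equal(error_bound(2, rho = 0.8, P, u_bar = 0, alpha = 1, t = ts),
               2 * exp(-0.8 * ts), tolerance = 1e-8)
  expect_equal(error_bound(1, rho = 0.5, P, u_bar = 0, alpha = 0.7, t = 4),
               mittag_leffler(0.7, -0.5 * 4^0.7), tolerance = 1e-10)
  expect_error(error_bound(1, rho = -0.1, P, u_bar = 0, alpha = 1, t = 1), "rho")
})

test_that("fractional and exponential bounds cross over in time", {
  rho <- 0.6
  short <- mittag_leffler(0.7, -rho * 0.1^0.7) < exp(-rho * 0.1)
  long <- mittag_leffler(0.7, -rho * 8^0.7) > exp(-rho * 8)
  expect_true(short)   # faster initial decay for alpha < 1
  expect_true(long)    # heavier algebraic tail at large t
})

test_that("Lyapunov traces are quadratic forms and decay for stable dynamics", {
  expect_equal(lyapunov_trace(matrix(0, 3, 2), diag(2)), rep(0, 3))
  e <- matrix(rnorm(10), 5, 2)
  expect_equal(lyapunov_trace(e, diag(2)), rowSums(e^2))
  sim <- simulate_error_dynamics(C = 0.8, W = 0, e0 = 1, u_bar = 0,
                                 alpha = 1, dt = 0.02, n_steps = 200)
  expect_true(all(diff(sim$V) <= 1e-12))
})

test_that("simulated disturbed error dynamics never exceed the certified bound", {
  for (sd in 1:20) {
    set.seed(400 + sd)
    n <- 6
    cvec <- runif(n, 0.6, 1.2)
    W <- matrix(rnorm(n * n, sd = 0.08), n); W <- (W + t(W)) / 2
    alpha <- c(0.7, 1)[1 + sd %% 2]
    sim <- simulate_error_dynamics(cvec, W, F = 1, e0 = rnorm(n), u_bar = 0.05,
                                   alpha = alpha, dt = 0.02, n_steps = 250,
                                   seed = sd)
    expect_gt(sim$rho, 0)
    expect_true(all(sim$norms <= sim$bound + 1e-9))
  }
})
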