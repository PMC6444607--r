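test_that("soft_threshold matches its closed form", {
  expect_equal(soft_threshold(2, 1), 1)
  expect_equal(soft_threshold(-2, 1), -1)
  expect_equal(soft_threshold(0.3, 0.5), 0)
  v <- c(-3, -0.2, 0, 0.2, 3)
  expect_equal(soft_threshold(v, 0), v)
  # per-coordinate kappa
  expect_equal(soft_threshold(c(2, 2), c(0.5, 3)), c(1.5, 0))
  expect_error(soft_threshold(1, -0.1), "nonnegative")
})

test_that("prox_quadratic solves the ridge subproblem via the n x n route", {
  # zero fixed point
  cache <- quadratic_cache(diag(3), rep(0, 3))
  expect_equal(prox_quadratic(rep(0, 3), 1, cache), rep(0, 3))
  # scalar closed form (y + v/rho) / (1 + 1/rho) at X = I
  cache <- quadratic_cache(diag(3), c(3, 0, 0))
  expect_equal(prox_quadratic(rep(0, 3), 1, cache), c(1.5, 0, 0))
  expect_error(prox_quadratic(rep(0, 3), 0, cache), "positive")

  # dense direct solve oracle on a p >> n instance
  inst <- rand_instance(20, 60, seed = 101)
  cache <- quadratic_cache(inst$X, inst$y)
  for (rho in c(0.01, 1, 50)) {
    v <- rnorm(60)
    got <- prox_quadratic(v, rho, cache)
    want <- solve(crossprod(inst$X) + diag(1 / rho, 60),
                  drop(crossprod(inst$X, inst$y)) + v / rho)
    expect_lt(sqrt(sum((got - want)^2)) / sqrt(sum(want^2)), 1e-8)
  }
})

test_that("quadratic_cache factorization reconstructs the Gram matrix", {
  inst <- rand_instance(15, 40, seed = 7)
  cache <- quadratic_cache(inst$X, inst$y)
  G <- tcrossprod(inst$X)
  rec <- cache$Q %*% (cache$lambda * t(cache$Q))
  expect_lt(norm(rec - G, "F") / norm(G, "F"), 1e-8)
  expect_equal(cache$Xty, drop(crossprod(inst$X, inst$y)))
})

test_that("armijo line search accepts per the sufficient-decrease rule", {
  # orthonormal X: Lipschitz constant 1, rho = 1 accepted immediately
  set.seed(21)
  X <- qr.Q(qr(matrix(rnorm(100), 10, 10)))
  y <- rnorm(10)
  beta <- rnorm(10)
  grad <- drop(crossprod(X, X %*% beta - y))
  ls <- armijo_line_search(beta, function(r) beta - r * grad, X, y)
  expect_equal(ls$rho, 1)
  expect_equal(ls$n_trials, 1L)

  # stationary point: candidate equals beta, rho0 returned
  beta_star <- drop(solve(X, y))
  ls0 <- armijo_line_search(beta_star, function(r) beta_star, X, y,
                            config = fit_config(rho0 = 0.7))
  expect_equal(ls0$rho, 0.7)

  # largest eigenvalue 16: accepted rho equals the first halving trial that
  # satisfies the inequality, verified by independent evaluation of both
  # sides
  X16 <- 4 * X  # X'X = 16 I
  grad16 <- drop(crossprod(X16, X16 %*% beta - y))
  cand <- function(r) beta - r * grad16
  ls16 <- armijo_line_search(beta, cand, X16, y)
  f <- function(b) 0.5 * sum((X16 %*% b - y)^2)
  rho_direct <- 1
  repeat {
    z <- cand(rho_direct)
    d <- z - beta
    rhs <- f(beta) + sum(grad16 * d) + sum(d^2) / (2 * rho_direct)
    if (f(z) <= rhs + 1e-12 * (1 + abs(rhs))) break
    rho_direct <- rho_direct / 2
  }
  expect_equal(ls16$rho, rho_direct)
  expect_lte(ls16$rho, 1 / 16 * (1 + 1e-10))

  # candidate whose loss overflows is never accepted: floor reached
  expect_error(
    armijo_line_search(beta, function(r) beta + 1e200, X, y,
                       config = fit_config(rho_floor = 1e-4)),
    "divergence")
})

test_that("check_convergence implements the scaled infinity-norm rule", {
  st <- list(beta = c(1, 2), theta = c(1, 2), u = c(5, 5))
  expect_true(check_convergence(st, 1e-12))
  st$beta <- c(2, 2); st$u <- c(0, 0)
  expect_false(check_convergence(st, 1e-4))
  st <- list(beta = c(2e-4, 0), theta = c(0, 0), u = c(1, 0))
  expect_true(check_convergence(st, 1e-4))
})

test_that("admm_fit reproduces orthogonal-design and unpenalized limits", {
  # orthogonal design: theta_j = S_lambda(y_j)
  y <- c(3, -2, 0.5, 0)
  st <- admm_fit(diag(4), y, lam = 1,
                 config = fit_config(eps_admm = 1e-8))
  expect_equal(st$theta, c(2, -1, 0, 0), tolerance = 1e-6)
  expect_true(st$converged)

  # lambda -> 0 with square nonsingular X recovers least squares. eps_admm
  # must sit below the lambda*rho residual scale: at lambda = 0 exactly the
  # primal residual is identically -u and the stopping rule fires at once.
  set.seed(31)
  # well-conditioned X (singular values in [1, 2]) so the unpenalized
  # limit converges at a useful linear rate
  Q1 <- qr.Q(qr(matrix(rnorm(25), 5)))
  Q2 <- qr.Q(qr(matrix(rnorm(25), 5)))
  X <- Q1 %*% diag(seq(1, 2, length.out = 5)) %*% Q2
  yy <- rnorm(5)
  b_ls <- drop(solve(X, yy))
  st0 <- admm_fit(X, yy, lam = 1e-6,
                  config = fit_config(eps_admm = 1e-10, max_iter = 1e5))
  expect_equal(st0$theta, b_ls, tolerance = 1e-4)
})

test_that("admm_fit matches the convex-solver oracle and satisfies KKT", {
  skip_if_not_installed("glmnet")
  for (seed in 1:6) {
    inst <- rand_instance(30, 10 * seed, seed = 200 + seed)
    lam <- 0.5 * lambda_max(inst$X, inst$y)
    st <- admm_fit(inst$X, inst$y, lam,
                   config = fit_config(eps_admm = 1e-6, max_iter = 50000))
    b_oracle <- glmnet_oracle(inst$X, inst$y, lam)
    o1 <- lasso_obj(inst$X, inst$y, lam, st$theta)
    o2 <- lasso_obj(inst$X, inst$y, lam, b_oracle)
    expect_lt(abs(o1 - o2) / o2, 1e-4)
    expect_true(kkt_ok(inst$X, inst$y, lam, st$theta, tol = 1e-3))
  }
})

test_that("unit-weight and gamma = 0 adaptive fits coincide", {
  inst <- rand_instance(25, 40, seed = 77)
  lam <- 0.3 * lambda_max(inst$X, inst$y)
  w0 <- marginal_weights(inst$X, inst$y, gamma = 0)
  st_w <- admm_fit(inst$X, inst$y, lam, weights = w0)
  st_u <- admm_fit(inst$X, inst$y, lam, weights = rep(1, 40))
  expect_identical(st_w$theta, st_u$theta)
})

test_that("warm starts converge to the same objective as cold starts", {
  inst <- rand_instance(40, 80, seed = 55)
  lmax <- lambda_max(inst$X, inst$y)
  cfg <- fit_config(eps_admm = 1e-6, max_iter = 50000)
  cold <- admm_fit(inst$X, inst$y, 0.2 * lmax, config = cfg)
  prev <- admm_fit(inst$X, inst$y, 0.4 * lmax, config = cfg)
  warm <- admm_fit(inst$X, inst$y, 0.2 * lmax, config = cfg,
                   warm = list(beta = prev$beta, theta = prev$theta))
  expect_lt(abs(cold$objective - warm$objective) /
              abs(cold$objective), 1e-6)
})

test_that("training loss is non-decreasing in lambda", {
  inst <- rand_instance(30, 50, seed = 42)
  lmax <- lambda_max(inst$X, inst$y)
  lams <- lmax * c(0.01, 0.05, 0.1, 0.3, 0.6, 1)
  losses <- vapply(lams, function(l) {
    st <- admm_fit(inst$X, inst$y, l,
                   config = fit_config(eps_admm = 1e-6, max_iter = 50000))
    0.5 * sum((inst$X %*% st$theta - inst$y)^2)
  }, numeric(1))
  expect_true(all(diff(losses) > -1e-6 * max(losses)))
})

test_that("non-convergence is flagged, not raised", {
  inst <- rand_instance(10, 20, seed = 3)
  expect_warning(
    st <- admm_fit(inst$X, inst$y, 0.1 * lambda_max(inst$X, inst$y),
                   config = fit_config(max_iter = 2)),
    "max_iter")
  expect_false(st$converged)
  expect_equal(st$t, 2L)
})
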