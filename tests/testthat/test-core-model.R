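test_that("soft threshold shrinks toward zero and preserves sign", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_equal(soft_threshold(c(3, -0.5, -3), c(1, 1, 1)), c(2, 0, -2))
  expect_error(soft_threshold(1, -0.1), "nonnegative")
  expect_error(soft_threshold(c(1, 2), c(1, 1, 1)), "conformable")
})

test_that("objective matches its closed-form special cases", {
  inst <- rand_instance(101, n = 30, p = 12, m = 3)
  n <- nrow(inst$X)
  # all-zero coefficients: penalties vanish
  expect_equal(
    wsgl_objective(inst$X, inst$y, inst$groups, rep(0, 12), lambda = 0.3,
                   alpha = 0.5, weights = inst$w),
    sum(inst$y^2) / (2 * n))
  # lambda = 0: pure least-squares loss at any beta
  b <- rnorm(12)
  expect_equal(
    wsgl_objective(inst$X, inst$y, inst$groups, b, lambda = 0,
                   alpha = 0.5, weights = inst$w),
    sum((inst$y - inst$X %*% b)^2) / (2 * n))
  # alpha = 1 with unit weights: the 1/(2n)-scaled lasso objective
  expect_equal(
    wsgl_objective(inst$X, inst$y, inst$groups, b, lambda = 0.2,
                   alpha = 1, weights = 1),
    sum((inst$y - inst$X %*% b)^2) / (2 * n) + 0.2 * sum(abs(b)))
  expect_error(
    wsgl_objective(inst$X, inst$y, inst$groups, b[-1], 0.1),
    "length p")
})

test_that("group-zero screening follows the soft-thresholded bound", {
  inst <- rand_instance(202, n = 30, p = 9, m = 3)
  Xk <- inst$X[, inst$groups == 1, drop = FALSE]
  # perfect partial fit zeroes the group
  expect_true(group_is_zero(Xk, rep(0, 30), lambda = 0.1, alpha = 0.5,
                            weights = 1))
  # alpha = 0 reduces to the plain group-norm bound
  g <- crossprod(Xk, inst$y) / 30
  lam_edge <- sqrt(sum(g^2)) / sqrt(ncol(Xk))
  expect_true(group_is_zero(Xk, inst$y, lambda = lam_edge * 1.01,
                            alpha = 0, weights = 1))
  expect_false(group_is_zero(Xk, inst$y, lambda = lam_edge * 0.99,
                             alpha = 0, weights = 1))
})

test_that("just above lambda_max every group screens to zero and the oracle agrees", {
  inst <- rand_instance(303, n = 35, p = 15, m = 4)
  Xs <- std_design(inst$X)
  yc <- inst$y - mean(inst$y)
  lam <- lambda_max(inst$X, inst$y, inst$groups, alpha = 0.95,
                    weights = inst$w) * 1.001
  for (k in unique(inst$groups)) {
    expect_true(group_is_zero(Xs[, inst$groups == k, drop = FALSE], yc,
                              lambda = lam, alpha = 0.95,
                              weights = inst$w[inst$groups == k]))
  }
  bo <- oracle_wsgl(Xs, yc, inst$groups, lam, 0.95, inst$w)
  expect_lt(max(abs(bo)), 1e-8)
})

test_that("coordinate update matches 1-D closed forms", {
  # alpha = 1, standardized column with x'x/n = 1, x'y/n = 2, lambda 0.5:
  # the 1-D lasso solution is S(2, 0.5) = 1.5
  n <- 50
  set.seed(7)
  x <- rnorm(n)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  gam <- 2 * x  # makes x' gam / n = 2 exactly
  expect_equal(
    coordinate_update(x, gam, group_norm = 1, lambda = 0.5, alpha = 1),
    1.5)
  # zero condition |x' gamma| <= n alpha lambda omega
  gam_small <- 0.3 * x
  expect_equal(
    coordinate_update(x, gam_small, group_norm = 1, lambda = 0.5,
                      alpha = 1, weight = 1), 0)
  # lambda = 0: ordinary least-squares slope
  y1 <- 1.7 * x + rnorm(n, sd = 0.01)
  expect_equal(
    coordinate_update(x, y1, group_norm = 1, lambda = 0, alpha = 0.5),
    sum(x * y1) / sum(x^2))
  expect_error(coordinate_update(rep(0, n), gam, 1, 0.1), "zero-variance")
})

test_that("unpenalized fit recovers least squares and lambda_max kills the fit", {
  inst <- rand_instance(404, n = 40, p = 10, m = 3)
  fit0 <- fit_wsgl(inst$X, inst$y, inst$groups, lambda = 0, alpha = 0.95,
                   weights = inst$w, tol_coef = 1e-9, tol_obj = 1e-13)
  ls <- stats::lm.fit(cbind(1, inst$X), inst$y)$coefficients[-1]
  expect_equal(unname(fit0$beta), unname(ls), tolerance = 1e-6)

  lmax <- lambda_max(inst$X, inst$y, inst$groups, alpha = 0.95,
                     weights = inst$w)
  fitz <- fit_wsgl(inst$X, inst$y, inst$groups, lambda = lmax * 1.0001,
                   alpha = 0.95, weights = inst$w)
  expect_identical(unname(fitz$beta), rep(0, 10))
  fitnz <- fit_wsgl(inst$X, inst$y, inst$groups, lambda = lmax * 0.9,
                    alpha = 0.95, weights = inst$w)
  expect_gt(sum(fitnz$beta != 0), 0)
})

test_that("solver objective matches the proximal-gradient oracle", {
  for (seed in 1:6) {
    for (alpha in c(0, 0.5, 0.95, 1)) {
      inst <- rand_instance(seed * 13 + alpha * 100)
      Xs <- std_design(inst$X)
      yc <- inst$y - mean(inst$y)
      lam <- 0.08
      fit <- fit_wsgl(inst$X, inst$y, inst$groups, lambda = lam,
                      alpha = alpha, weights = inst$w,
                      tol_coef = 1e-8, tol_obj = 1e-12)
      bo <- oracle_wsgl(Xs, yc, inst$groups, lam, alpha, inst$w)
      o_fit <- oracle_objective(Xs, yc, inst$groups, fit$beta_std, lam,
                                alpha, inst$w)
      o_or <- oracle_objective(Xs, yc, inst$groups, bo, lam, alpha, inst$w)
      expect_lt(abs(o_fit - o_or) / o_or, 1e-6)
    }
  }
})

test_that("objective trace is non-increasing and fit is deterministic", {
  for (seed in c(11, 29)) {
    inst <- rand_instance(seed)
    fit <- fit_wsgl(inst$X, inst$y, inst$groups, lambda = 0.05,
                    alpha = 0.95, weights = inst$w)
    expect_true(all(diff(fit$objective_trace) <=
                      1e-10 * max(1, fit$objective_trace[1])))
    fit2 <- fit_wsgl(inst$X, inst$y, inst$groups, lambda = 0.05,
                     alpha = 0.95, weights = inst$w)
    expect_identical(fit$beta, fit2$beta)
  }
})

test_that("group norms are zero exactly when all group coefficients are", {
  inst <- rand_instance(555)
  fit <- fit_wsgl(inst$X, inst$y, inst$groups, lambda = 0.1, alpha = 0.9,
                  weights = inst$w)
  for (k in seq_along(fit$group_norms)) {
    in_k <- fit$group_index == k
    expect_identical(fit$group_norms[[k]] == 0, all(fit$beta[in_k] == 0))
  }
})

test_that("permuting loci (with group relabeling) permutes the solution", {
  inst <- rand_instance(666, n = 40, p = 18, m = 4)
  perm <- sample(18)
  fit1 <- fit_wsgl(inst$X, inst$y, inst$groups, lambda = 0.04,
                   alpha = 0.95, weights = inst$w,
                   tol_coef = 1e-9, tol_obj = 1e-13)
  fit2 <- fit_wsgl(inst$X[, perm], inst$y, inst$groups[perm], lambda = 0.04,
                   alpha = 0.95, weights = inst$w[perm],
                   tol_coef = 1e-9, tol_obj = 1e-13)
  expect_equal(unname(fit2$beta), unname(fit1$beta[perm]), tolerance = 1e-6)
})

test_that("support shrinks along an increasing lambda path", {
  inst <- rand_instance(777, n = 40, p = 20, m = 4)
  lmax <- lambda_max(inst$X, inst$y, inst$groups, alpha = 0.95,
                     weights = inst$w)
  grid <- lmax * c(0.05, 0.2, 0.5, 0.999, 1.01)
  sizes <- vapply(grid, function(l) {
    sum(fit_wsgl(inst$X, inst$y, inst$groups, lambda = l, alpha = 0.95,
                 weights = inst$w)$beta != 0)
  }, 0)
  expect_identical(sizes[5], 0)
  expect_lte(sizes[4], 3)           # at 0.999 * lambda_max: 0 or small
  expect_gte(sizes[1], sizes[4])    # endpoints of the weak-monotone trend
})

test_that("input contracts are enforced", {
  inst <- rand_instance(888, n = 20, p = 6, m = 2)
  expect_error(fit_wsgl(inst$X, inst$y[-1], inst$groups, lambda = 0.1,
                        weights = 1), "match")
  expect_error(fit_wsgl(inst$X, inst$y, inst$groups[-1], lambda = 0.1,
                        weights = 1), "every locus")
  expect_error(fit_wsgl(inst$X, inst$y, inst$groups, lambda = -1,
                        weights = 1), "lambda")
  expect_error(fit_wsgl(inst$X, inst$y, inst$groups, lambda = 0.1,
                        alpha = 2, weights = 1), "alpha")
  Xc <- inst$X
  Xc[, 2] <- 1
  expect_error(fit_wsgl(Xc, inst$y, inst$groups, lambda = 0.1, weights = 1),
               "zero-variance")
  Xn <- inst$X
  Xn[1, 1] <- NA
  expect_error(fit_wsgl(Xn, inst$y, inst$groups, lambda = 0.1, weights = 1),
               "missing")
})
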