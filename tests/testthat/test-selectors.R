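test_that("graphical LASSO handles the analytic corner cases", {
  # diagonal covariance: empty graph at any positive penalty
  fit <- glasso_solve(diag(c(1, 2, 3)), penalty = 0.05)
  expect_equal(sum(fit$selection), 0)
  expect_equal(fit$Theta, diag(1 / c(1, 2, 3)), tolerance = 1e-6,
               ignore_attr = TRUE)

  # penalty at the largest absolute off-diagonal: empty graph
  sim <- simulate_graph_data(n = 60, p = 12, nu = 0.2, seed = 1)
  S <- cor(sim$X)
  lmax <- max(abs(S[upper.tri(S)]))
  expect_equal(sum(glasso_solve(S, lmax)$selection), 0)
  expect_gt(sum(glasso_solve(S, lmax * 0.3)$selection), 0)
})

test_that("constant penalty matrix reproduces the scalar solve", {
  sim <- simulate_graph_data(n = 80, p = 10, nu = 0.25, seed = 2)
  S <- cor(sim$X)
  lam <- 0.2
  Lmat <- matrix(lam, 10, 10)
  diag(Lmat) <- 0
  f_scalar <- glasso_solve(S, lam, tol = 1e-6)
  f_matrix <- glasso_solve(S, Lmat, tol = 1e-6)
  expect_equal(f_scalar$selection, f_matrix$selection)
  expect_equal(f_scalar$Theta, f_matrix$Theta, tolerance = 1e-6)
})

test_that("solver matches an independent proximal-gradient oracle", {
  set.seed(3)
  x <- matrix(rnorm(200 * 5), 200, 5) %*%
    chol(corr_from_upper(c(.4, .2, .1, .3, .2, .5, .1, .2, .1, .3), 5))
  S <- cor(x)

  # scalar penalty (off-diagonal only)
  Lambda <- matrix(0.1, 5, 5)
  diag(Lambda) <- 0
  fit <- glasso_solve(S, 0.1, tol = 1e-7)
  oracle <- ista_glasso(S, Lambda)
  expect_lt(abs(glasso_objective(fit$Theta, S, Lambda) -
                  glasso_objective(oracle, S, Lambda)), 1e-4)

  # elementwise penalty matrix
  set.seed(4)
  Lam2 <- matrix(runif(25, 0.05, 0.3), 5, 5)
  Lam2 <- (Lam2 + t(Lam2)) / 2
  diag(Lam2) <- 0
  fit2 <- glasso_solve(S, Lam2, tol = 1e-7)
  oracle2 <- ista_glasso(S, Lam2)
  expect_lt(abs(glasso_objective(fit2$Theta, S, Lam2) -
                  glasso_objective(oracle2, S, Lam2)), 1e-4)
})

test_that("objective is monotone across sweeps and the gap closes", {
  sim <- simulate_graph_data(n = 100, p = 15, nu = 0.15, seed = 5)
  S <- cor(sim$X)
  fit <- glasso_solve(S, 0.1, tol = 1e-6, trace_objective = TRUE)
  tr <- fit$objective_trace
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) > -1e-6))
  expect_lt(abs(fit$gap), 1e-3)
  expect_true(fit$converged)
})

test_that("support shrinks as a constant penalty grows", {
  sim <- simulate_graph_data(n = 100, p = 15, nu = 0.2, seed = 6)
  S <- cor(sim$X)
  sizes <- sapply(c(0.05, 0.1, 0.2, 0.4, 0.7), function(l) {
    sum(glasso_solve(S, l)$selection)
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("penalty grids span empty to dense models", {
  sim <- simulate_graph_data(n = 150, p = 20, nu = 0.15, seed = 7)
  g <- make_lambda_grid(sim$X, algorithm = "glasso", size = 20)
  expect_s3_class(g, "lambda_grid")
  expect_true(all(diff(g$values) < 0))
  S <- cor(sim$X)
  warm <- NULL
  dens <- sapply(g$values, function(l) {
    fit <- glasso_solve(S, l, warm = warm)
    warm <<- fit
    mean(fit$selection)
  })
  expect_equal(dens[1], 0)
  expect_gte(max(dens), 0.5)
  expect_gt(length(unique(round(dens, 3))), 10) # non-trivially spread

  # lasso grid errors
  set.seed(8)
  x <- matrix(rnorm(50 * 5), 50, 5)
  qrx <- qr.Q(qr(cbind(1, x)))
  y_orth <- rnorm(50)
  y_orth <- y_orth - qrx %*% crossprod(qrx, y_orth) # orthogonal to x and 1
  expect_error(make_lambda_grid(x, as.vector(y_orth), algorithm = "lasso"),
               "orthogonal")
  xc <- cbind(x, 1)
  expect_error(make_lambda_grid(xc, rnorm(50), algorithm = "lasso"),
               "constant feature")
})

test_that("lasso selection respects the penalty path endpoints", {
  sim <- simulate_regression_data(n = 100, p = 8, n_true = 3, seed = 9)
  g <- make_lambda_grid(sim$X, sim$y, algorithm = "lasso", size = 10)
  sel <- lasso_select(sim$X, sim$y, g)
  expect_equal(dim(sel), c(8, 10))
  expect_true(all(sel %in% c(0, 1)))
  # largest penalty: empty model
  expect_equal(sum(sel[, 1]), 0)

  # penalty zero with n > p and full rank: the OLS support (everything)
  sel0 <- lasso_select(sim$X, sim$y, c(g$values[1], 1e-8))
  expect_equal(sum(sel0[, 2]), 8)

  expect_error(lasso_select(sim$X, sim$y[-1], g), "row-aligned")
  expect_error(lasso_select(sim$X[1, , drop = FALSE], sim$y[1], g),
               "2 observations")
})

test_that("true effects enter the lasso path before null features", {
  ranks_true <- ranks_null <- NULL
  for (seed in 1:20) {
    sim <- simulate_regression_data(n = 100, p = 50, n_true = 10,
                                    effect_scheme = "mixed",
                                    r2_target = 0.7, seed = seed)
    g <- make_lambda_grid(sim$X, sim$y, algorithm = "lasso", size = 25)
    sel <- lasso_select(sim$X, sim$y, g)
    entry <- apply(sel, 1, function(r) {
      w <- which(r == 1)
      if (length(w)) min(w) else ncol(sel) + 1
    })
    ranks_true <- c(ranks_true, mean(entry[sim$support]))
    ranks_null <- c(ranks_null, mean(entry[-sim$support]))
  }
  expect_true(all(ranks_true < ranks_null))
})
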