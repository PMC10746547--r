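test_that("edge enumeration is bijective and row-major", {
  for (p in c(2, 4, 7, 30)) {
    ep <- edge_pairs(p)
    expect_equal(nrow(ep), p * (p - 1) / 2)
    expect_equal(edge_index(ep[, 1], ep[, 2], p), seq_len(nrow(ep)))
    expect_equal(edge_index(ep[, 2], ep[, 1], p), seq_len(nrow(ep)))
  }
  expect_equal(edge_pairs(4)[1:3, 2], c(2L, 3L, 4L)) # (1,2),(1,3),(1,4) first
  expect_error(edge_index(1, 1, 5), "i != j")
})

test_that("scale-free graphs are trees with p - 1 edges for every seed", {
  for (seed in 1:20) {
    theta <- simulate_adjacency(100, topology = "scale-free", seed = seed)
    expect_equal(sum(theta[upper.tri(theta)]), 99)
    expect_true(all(theta == t(theta)))
    expect_true(all(diag(theta) == 0))
  }
})

test_that("Erdos-Renyi density matches the binomial expectation", {
  theta0 <- simulate_adjacency(100, nu = 0, seed = 1)
  expect_equal(sum(theta0), 0)
  set.seed(42)
  counts <- replicate(1000, {
    theta <- simulate_adjacency(40, nu = 0.05)
    sum(theta[upper.tri(theta)])
  })
  m <- 40 * 39 / 2
  expected <- m * 0.05
  se <- sqrt(m * 0.05 * 0.95 / 1000)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("precision construction follows the diagonal-dominance recipe", {
  omega <- build_precision(single_edge_theta(), u = 0.1, seed = 1)
  expect_equal(abs(omega[1, 2]), 1)
  expect_equal(diag(omega), abs(omega[1, 2]) + c(0.1, 0.1),
               ignore_attr = TRUE)
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), c(0.1, 2.1), tolerance = 1e-12)

  # empty graph: identity scaled by u
  empty <- matrix(0, 4, 4)
  expect_equal(build_precision(empty, u = 1), diag(4), ignore_attr = TRUE)

  # cross-group scaling
  theta <- matrix(0, 4, 4)
  theta[1, 3] <- theta[3, 1] <- 1
  om <- build_precision(theta, groups = c(1, 1, 2, 2), vb = 0.2, u = 0.5,
                        seed = 2)
  expect_equal(abs(om[1, 3]), 0.2)
})

test_that("simulated precision matrices are positive definite", {
  set.seed(7)
  for (i in 1:100) {
    theta <- simulate_adjacency(20, nu = 0.2)
    u <- runif(1, 0.01, 2)
    omega <- build_precision(theta, u = u)
    ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    # Gershgorin: smallest eigenvalue at least the dominance margin u
    expect_gte(min(ev), u - 1e-10)
  }
})

test_that("contrast counts unique truncated correlations", {
  expect_equal(contrast(diag(5)), 1)
  expect_equal(contrast(corr_from_upper(0.3, 2)), 1)
  # 0.1234 and 0.1236 truncate to the same value, 0.5 differs
  C <- corr_from_upper(c(0.1234, 0.1236, 0.5), 3)
  expect_equal(contrast(C), 2)
  # truncation is toward zero, not rounding
  C2 <- corr_from_upper(c(0.1239, 0.1231, -0.1239), 3)
  expect_equal(contrast(C2), 2) # {0.123, 0.123, -0.123}
  expect_error(contrast(matrix(1:4, 2)), "symmetric")
})

test_that("u tuning maximises contrast with ties toward smaller u", {
  theta <- simulate_adjacency(20, nu = 0.1, seed = 3)
  grid <- exp(seq(log(1e-5), log(100), length.out = 20))
  set.seed(11)
  alpha <- stabcal:::.draw_alpha(20)
  chosen <- tune_u(theta, u_grid = grid, alpha = alpha)
  # brute force over the same grid and signs
  scores <- sapply(grid, function(u) {
    om <- build_precision(theta, u = u, alpha = alpha)
    contrast(cov2cor(solve(om)))
  })
  expect_equal(chosen, grid[which.max(scores)])

  expect_equal(tune_u(theta, u_grid = 0.7, alpha = alpha), 0.7)
  empty <- matrix(0, 6, 6)
  # constant contrast: smallest grid value wins
  expect_equal(tune_u(empty, u_grid = c(0.5, 0.1, 2), seed = 1), 0.1)
  expect_error(tune_u(theta, u_grid = numeric(0)), "nonempty")
})

test_that("graph data generation is seeded and matches its covariance", {
  a <- simulate_graph_data(n = 30, p = 10, nu = 0.2, seed = 5)
  b <- simulate_graph_data(n = 30, p = 10, nu = 0.2, seed = 5)
  expect_identical(a$X, b$X)
  expect_equal(a$omega %*% a$sigma, diag(10), tolerance = 1e-8,
               ignore_attr = TRUE)
  # support of omega equals theta off the diagonal
  off <- a$omega
  diag(off) <- 0
  expect_equal(1 * (abs(off) > 1e-12), a$theta, ignore_attr = TRUE)

  # law of large numbers: empirical covariance approaches the target
  # (u fixed at 1 so covariance entries have magnitude near one and an
  # absolute tolerance is meaningful)
  big <- simulate_graph_data(n = 1e5, p = 3, nu = 0.8, u = 1, seed = 6)
  expect_lt(max(abs(cov(big$X) - big$sigma)), 0.05)
})

test_that("two-group simulation scales between-group precision entries", {
  sim <- simulate_graph_data(n = 10, p = 30, nu = 0.2,
                             groups = rep(1:2, each = 15), seed = 8)
  expect_equal(sim$vb, 0.2)
  cross <- outer(rep(1:2, each = 15), rep(1:2, each = 15), `!=`)
  vals_cross <- abs(sim$omega[cross & sim$theta == 1])
  vals_within <- abs(sim$omega[!cross & sim$theta == 1 &
                                 upper.tri(sim$omega)])
  expect_true(all(abs(vals_cross - 0.2) < 1e-12))
  expect_true(all(abs(vals_within - 1) < 1e-12))
})

test_that("regression noise level hits the target explained variance", {
  sim <- simulate_regression_data(n = 100, p = 20, n_true = 5,
                                  r2_target = 0.8, seed = 1)
  expect_equal(sim$sigma_noise, sqrt((1 - 0.8) / 0.8 * sim$s2))
  # the formula inverts exactly
  expect_equal(sim$s2 / (sim$s2 + sim$sigma_noise^2), 0.8)
  expect_equal(length(sim$support), 5)
  expect_true(all(sim$beta[-sim$support] == 0))

  # mixed effects have magnitude in [0.5, 1]
  mags <- abs(sim$beta[sim$support])
  expect_true(all(mags >= 0.5 & mags <= 1))

  # binary effects are exactly +-1
  simb <- simulate_regression_data(n = 50, p = 10, n_true = 4,
                                   effect_scheme = "binary", seed = 2)
  expect_true(all(abs(simb$beta[simb$support]) == 1))

  # Monte-Carlo: oracle OLS on the true support recovers the target R2
  simo <- simulate_regression_data(n = 1e4, p = 20, n_true = 5,
                                   r2_target = 0.7, seed = 3)
  fit <- lm(simo$y ~ simo$X[, simo$support])
  expect_lt(abs(summary(fit)$r.squared - 0.7), 0.02)

  expect_error(simulate_regression_data(n = 50, p = 10, n_true = 4,
                                        r2_target = 1.2), "r2_target")
})
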