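test_that("block structure enumerates within and cross blocks", {
  bs <- block_index_sets(c(1, 1, 2, 2))
  expect_equal(bs$G, 2)
  expect_equal(bs$B, 3)
  # edges in row-major order: (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  expect_equal(bs$block_of_edge, c(1L, 2L, 2L, 2L, 2L, 3L))
  expect_equal(bs$block_sizes, c(1L, 4L, 1L))
  expect_true(all(tabulate(bs$block_of_edge, 3) == bs$block_sizes))

  expect_equal(block_index_sets(rep(1:3, each = 2))$B, 6)
  expect_error(block_index_sets(c(1, 1, 2)), "at least 2")

  # blocks partition the edge universe
  bs2 <- block_index_sets(rep(1:3, times = c(3, 4, 5)))
  expect_equal(sum(bs2$block_sizes), 12 * 11 / 2)
})

test_that("block penalty matrices place penalties by edge block", {
  bs <- block_index_sets(c(1, 1, 2, 2))
  P <- block_penalty_matrix(bs, b = 2, lambda_b = 0.7, lambda0 = 0.1)
  expect_true(all(diag(P) == 0))
  expect_equal(P[1, 3], 0.7)
  expect_equal(P[2, 4], 0.7)
  expect_equal(P[1, 2], 0.1)
  expect_equal(P[3, 4], 0.1)
  expect_equal(P, t(P))
  # equal penalties collapse to a constant matrix
  Pc <- block_penalty_matrix(bs, b = 1, lambda_b = 0.3, lambda0 = 0.3)
  expect_true(all(Pc[upper.tri(Pc)] == 0.3))
})

test_that("equal weak and block penalties reproduce single-block counts", {
  sim <- simulate_graph_data(n = 60, p = 10, nu = 0.2,
                             groups = rep(1:2, each = 5), seed = 41)
  bs <- block_index_sets(rep(1:2, each = 5))
  lam <- c(0.5, 0.3)
  res <- draw_resamples(60, K = 4, seed = 42)
  cors <- stabcal:::.resample_correlations(sim$X, res, "subsample")
  cnt <- selection_counts(sim$X, algorithm = "glasso", lambda = lam,
                          K = 4, seed = 42, tol = 1e-5)
  for (b in 1:3) {
    # with lambda0 = lambda_b the block penalty matrix is constant, so
    # block counts must match the single-block run restricted to the block
    for (l in 1:2) {
      Hb1 <- stabcal:::.block_counts(cors, bs, b, lam[l], lambda0 = lam[l],
                                     tol = 1e-5, max_iter = 100)
      expect_equal(as.vector(Hb1),
                   unname(cnt$H[bs$block_of_edge == b, l]))
    }
  }
})

test_that("multi-block calibration returns coherent block results", {
  sim <- simulate_graph_data(n = 80, p = 20, nu = 0.15,
                             groups = rep(1:2, each = 10), seed = 43)
  fit <- stabsel_multiblock(sim$X, rep(1:2, each = 10), K = 10,
                            n_lambda = 8, seed = 44)
  expect_s3_class(fit, "stabsel_multiblock")
  expect_length(fit$per_block, 3)

  # the union graph restricted to each block is that block's stable set
  ep <- edge_pairs(20)
  adj_edges <- fit$adjacency[ep] == 1
  for (b in 1:3) {
    inb <- fit$blocks$block_of_edge == b
    expect_equal(adj_edges[inb], unname(fit$per_block[[b]]$stable))
  }
  expect_output(print(fit), "Multi-block")

  # edge-list export carries one row per candidate edge
  path <- tempfile(fileext = ".csv")
  write_multiblock_edges(fit, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 190)
  expect_equal(sum(df$stable_flag), sum(fit$stable))
  unlink(path)
})

test_that("a single group reduces the multi-block model to single-block", {
  sim <- simulate_graph_data(n = 70, p = 10, nu = 0.25, seed = 45)
  single <- stabsel(sim$X, algorithm = "glasso", K = 8, n_lambda = 6,
                    seed = 46)
  multi <- stabsel_multiblock(sim$X, groups = rep(1, 10), K = 8,
                              n_lambda = 6, seed = 46)
  expect_equal(multi$blocks$B, 1)
  expect_equal(multi$per_block[[1]]$lambda, single$lambda,
               tolerance = 1e-10)
  expect_equal(unname(multi$proportions), unname(single$proportions))
  expect_equal(multi$per_block[[1]]$lambda_hat, single$lambda_hat)
  expect_equal(multi$per_block[[1]]$pi_hat, single$pi_hat)
  expect_equal(unname(multi$stable), unname(single$stable))
})

test_that("joint product-grid calibration agrees with single-block at B = 1", {
  sim <- simulate_graph_data(n = 70, p = 8, nu = 0.3, seed = 47)
  joint <- stabsel_joint_blocks(sim$X, groups = rep(1, 8), K = 6,
                                n_lambda = 5, seed = 48)
  expect_equal(joint$blocks$B, 1)
  # same counts machinery: scores coincide with a direct surface on the
  # same penalty grid
  cnt <- selection_counts(sim$X, algorithm = "glasso",
                          lambda = sort(joint$grids[[1]],
                                        decreasing = TRUE),
                          K = 6, seed = 48)
  surf <- score_surface(cnt)
  cal <- calibrate_surface(surf)
  expect_equal(unname(joint$lambda_hat), cal$lambda_hat)
  expect_equal(joint$score_max, cal$score_max, tolerance = 1e-8)

  expect_error(stabsel_joint_blocks(sim$X, groups = rep(1:4, each = 2),
                                    max_blocks = 3),
               "capped")
})

test_that("per-block PFER budgets keep the total bound below eta", {
  sim <- simulate_graph_data(n = 80, p = 20, nu = 0.15,
                             groups = rep(1:2, each = 10), seed = 49)
  eta <- 30
  fit <- stabsel_multiblock(sim$X, rep(1:2, each = 10), K = 10,
                            n_lambda = 8, pfer = "mb", eta = eta,
                            seed = 50)
  bounds <- vapply(fit$per_block, function(pb) pb$calibration$bound,
                   numeric(1))
  shares <- eta * fit$blocks$block_sizes / fit$blocks$N
  expect_true(all(bounds <= shares + 1e-12))
  expect_lte(fit$total_bound, eta)
})
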