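test_that("average model size rounds half-up", {
  expect_equal(model_size_q(c(100, 100, 50, rep(0, 7)), K = 100), 3L)
  expect_equal(model_size_q(rep(0, 5), K = 10), 0L)
  expect_equal(model_size_q(c(100, 49), K = 100), 1L) # mean 1.49
  expect_equal(model_size_q(c(100, 50), K = 100), 2L) # mean 1.50
  expect_error(model_size_q(c(5, 20), K = 10), "0, K")
})

test_that("stability score matches the brute-force binomial likelihood", {
  # N = 2, K = 10, H = (10, 0), pi = 0.8: q = 1, gamma = 0.5;
  # P(X >= 8) = P(X <= 2) = 56/1024 for X ~ B(10, 0.5)
  p_tail <- sum(choose(10, 8:10)) / 2^10
  expect_equal(p_tail, 56 / 1024)
  expect_equal(stability_score(c(10, 0), K = 10, pi = 0.8),
               -log(p_tail^2), tolerance = 1e-6)

  # empty and saturated models are uninformative
  expect_equal(stability_score(rep(0, 20), K = 10, pi = 0.8), 0)
  expect_equal(stability_score(rep(10, 20), K = 10, pi = 0.8), 0)

  # general case against a direct likelihood computation
  set.seed(1)
  for (i in 1:20) {
    K <- sample(10:60, 1)
    N <- sample(5:40, 1)
    h <- sample(0:K, N, replace = TRUE)
    pi <- runif(1, 0.55, 0.95)
    q <- floor(sum(h) / K + 0.5)
    gamma <- q / N
    f_hi <- pbinom(ceiling(K * pi) - 1, K, gamma)
    f_lo <- pbinom(floor(K * (1 - pi)), K, gamma)
    ll <- sum(ifelse(h >= K * pi, log(1 - f_hi),
                     ifelse(h <= K * (1 - pi), log(f_lo),
                            log(f_hi - f_lo))))
    if (is.finite(ll)) {
      # the linear-space reference loses precision when a CDF is near 1,
      # so compare at a tolerance the reference itself supports
      expect_equal(stability_score(h, K = K, pi = pi), -ll,
                   tolerance = 1e-5)
    }
  }

  expect_error(stability_score(c(1, 2), K = 10, pi = 0.4), "0.5, 1")
})

test_that("score survives probability underflow at sparse models", {
  # a strongly stable sparse model: tail probabilities underflow double
  # precision in linear space but the log-scale score must stay finite
  h <- c(rep(100, 10), rep(0, 4940))
  s <- stability_score(h, K = 100, pi = 0.9)
  expect_true(is.finite(s) && s > 0)
  # oracle on the log scale
  gamma <- 10 / 4950
  log_sel <- pbinom(89, 100, gamma, lower.tail = FALSE, log.p = TRUE)
  log_exc <- pbinom(10, 100, gamma, log.p = TRUE)
  expect_equal(s, -(10 * log_sel + 4940 * log_exc), tolerance = 1e-8)
})

test_that("score is invariant to feature permutation", {
  set.seed(2)
  h <- sample(0:50, 30, replace = TRUE)
  s1 <- stability_score(h, K = 50, pi = 0.75)
  s2 <- stability_score(sample(h), K = 50, pi = 0.75)
  expect_equal(s1, s2)
})

test_that("PFER bounds reproduce the closed forms", {
  expect_equal(pfer_mb(q = 10, pi = 0.75, N = 100), 2, tolerance = 1e-9)
  expect_equal(pfer_mb(q = 20, pi = 0.9, N = 400), 1.25, tolerance = 1e-9)
  expect_equal(pfer_mb(q = 0, pi = 0.8, N = 50), 0)
  expect_equal(pfer_ss(q = 10, pi = 0.75, N = 100, K = 100), 50 / 49,
               tolerance = 1e-9)
  expect_equal(pfer_ss(q = 10, pi = 0.9, N = 100, K = 100), 22 / 51,
               tolerance = 1e-9)
  expect_equal(pfer_ss(q = 0, pi = 0.7, N = 100, K = 100), 0)
  expect_error(pfer_mb(q = 1, pi = 0.5, N = 10), "0.5")
  expect_error(pfer_ss(q = 1, pi = 0.505, N = 10, K = 50), "denominator")
})

test_that("PFER bounds decrease in pi and the SS bound is stricter", {
  pi_grid <- pi_grid_default()
  for (q in c(5, 20, 80)) {
    mb <- pfer_mb(q, pi_grid, N = 200)
    ss <- pfer_ss(q, pi_grid, N = 200, K = 100)
    expect_true(all(diff(mb) < 0))
    expect_true(all(diff(ss) < 0))
    expect_true(all(ss < mb))
  }
})

test_that("surface cells agree with the standalone score", {
  set.seed(3)
  H <- matrix(sample(0:25, 40 * 6, replace = TRUE), 40, 6)
  colnames(H) <- signif(seq(0.9, 0.1, length.out = 6), 6)
  surf <- score_surface(H, K = 25)
  expect_equal(length(surf$pi_grid), 31)
  expect_equal(range(surf$pi_grid), c(0.6, 0.9))
  expect_true(all(surf$score >= 0))
  expect_equal(surf$gamma, surf$q / 40)
  for (l in seq_len(6)) {
    for (m in c(1, 10, 31)) {
      expect_equal(surf$score[l, m],
                   stability_score(H[, l], K = 25, pi = surf$pi_grid[m]))
      expect_equal(surf$pfer_mb[l, m],
                   pfer_mb(surf$q[l], surf$pi_grid[m], 40))
      expect_equal(surf$pfer_ss[l, m],
                   pfer_ss(surf$q[l], surf$pi_grid[m], 40, 25))
    }
  }
})

test_that("two-category variant drops the stable-exclusion information", {
  h <- c(rep(20, 3), rep(1, 5), rep(0, 12))
  s3 <- stability_score(h, K = 20, pi = 0.8)
  s2 <- stability_score(h, K = 20, pi = 0.8, two_categories = TRUE)
  expect_true(s2 > 0 && s3 > 0 && !isTRUE(all.equal(s2, s3)))
  # two-category oracle
  gamma <- model_size_q(h, 20) / 20
  log_sel <- pbinom(15, 20, gamma, lower.tail = FALSE, log.p = TRUE)
  log_oth <- pbinom(15, 20, gamma, log.p = TRUE)
  expect_equal(s2, -(3 * log_sel + 17 * log_oth), tolerance = 1e-8)
})
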