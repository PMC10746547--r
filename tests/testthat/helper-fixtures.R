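# Small fixtures shared across test files; everything is generated in code.

# a tiny two-node adjacency with one edge
single_edge_theta <- function() {
  theta <- matrix(0, 2, 2)
  theta[1, 2] <- theta[2, 1] <- 1
  theta
}

# symmetric unit-diagonal matrix from a vector of upper-triangular entries
corr_from_upper <- function(vals, p) {
  stopifnot(length(vals) == p * (p - 1) / 2)
  C <- diag(p)
  C[upper.tri(C)] <- vals
  C[lower.tri(C)] <- t(C)[lower.tri(C)]
  C
}

# independent proximal-gradient (ISTA) solver for the penalised Gaussian
# log-likelihood; slow but derived from the objective alone, so it serves
# as an oracle for the block-coordinate-descent solver at small p
ista_glasso <- function(S, Lambda, n_iter = 50000, step = 0.01) {
  p <- nrow(S)
  theta <- diag(1 / diag(S))
  soft <- function(m, t) sign(m) * pmax(abs(m) - t, 0)
  for (i in seq_len(n_iter)) {
    grad <- solve(theta) - S
    prop <- theta + step * grad
    prop <- soft(prop, step * Lambda)
    prop <- (prop + t(prop)) / 2
    ok <- min(eigen(prop, symmetric = TRUE, only.values = TRUE)$values) > 1e-10
    if (ok) theta <- prop else step <- step / 2
  }
  theta
}

glasso_objective <- function(theta, S, Lambda) {
  as.numeric(determinant(theta, logarithm = TRUE)$modulus) -
    sum(S * theta) - sum(Lambda * abs(theta))
}

# metrics of a stable edge set against a simulated truth
edge_truth <- function(sim) {
  sim$theta[edge_pairs(sim$p)] == 1
}
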