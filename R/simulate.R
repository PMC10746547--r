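#' Simulate a binary adjacency matrix
#'
#' Random graphs are drawn from the Erdos-Renyi model, where each of the
#' \code{p*(p-1)/2} possible edges is independently present with probability
#' \code{nu}. Scale-free graphs are grown by Barabasi-Albert preferential
#' attachment, adding one edge per incoming node, which yields a connected
#' tree with exactly \code{p - 1} edges (\code{nu} is ignored).
#'
#' @param p number of nodes (>= 2).
#' @param nu edge density in [0, 1] (Erdos-Renyi only).
#' @param topology \code{"random"} (Erdos-Renyi) or \code{"scale-free"}
#'   (Barabasi-Albert).
#' @param seed optional integer seed; when \code{NULL} the current RNG stream
#'   is used, so callers can thread a single seed through a whole simulation.
#' @return symmetric 0/1 matrix with zero diagonal and dimnames
#'   \code{var1..varp}.
#' @export
#' @examples
#' theta <- simulate_adjacency(10, nu = 0.2, seed = 1)
#' sum(theta[upper.tri(theta)])
simulate_adjacency <- function(p, nu = 0.02,
                               topology = c("random", "scale-free"),
                               seed = NULL) {
  p <- .check_count(p, min = 2L, what = "p")
  topology <- match.arg(topology)
  nu <- .check_prob(nu, "nu")
  if (!is.null(seed)) set.seed(seed)

  theta <- matrix(0L, p, p)
  if (topology == "random") {
    ep <- edge_pairs(p)
    on <- stats::runif(nrow(ep)) < nu
    theta[ep[on, , drop = FALSE]] <- 1L
  } else {
    g <- igraph::sample_pa(p, power = 1, m = 1, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    theta[el] <- 1L
  }
  theta <- theta + t(theta)
  theta[theta > 1L] <- 1L
  dimnames(theta) <- list(paste0("var", seq_len(p)), paste0("var", seq_len(p)))
  theta
}

#' Contrast of a correlation matrix
#'
#' The contrast is the number of unique values among the off-diagonal
#' upper-triangular correlation coefficients once truncated (toward zero) to
#' three decimal digits. A correlation matrix with near-binary entries (all
#' correlations collapsing onto a few values) has low contrast; realistic
#' correlation matrices have high contrast. Used to tune the
#' diagonal-dominance constant \code{u} of the simulated precision matrix.
#'
#' @param correlation square symmetric matrix with unit diagonal.
#' @return integer count of unique truncated coefficients.
#' @export
#' @examples
#' contrast(diag(5)) # 1
contrast <- function(correlation) {
  correlation <- .check_matrix(correlation, "correlation")
  if (!.is_symmetric(correlation)) stop("'correlation' must be symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-8) {
    stop("'correlation' must have unit diagonal")
  }
  vals <- correlation[upper.tri(correlation)]
  length(unique(trunc(vals * 1000) / 1000))
}

# Off-diagonal precision entries for a fixed sign pattern alpha:
# alpha_ij within-group (or no groups), alpha_ij * vb between groups.
# Returns the symmetric off-diagonal part (zero diagonal).
.precision_offdiag <- function(theta, alpha, groups, vb) {
  off <- theta * alpha
  if (!is.null(groups)) {
    cross <- outer(groups, groups, `!=`)
    off[cross] <- off[cross] * vb
  }
  off
}

# diagonal dominance: Omega_ii = sum_j |Omega_ij| + u
.precision_with_u <- function(off, u) {
  omega <- off
  diag(omega) <- rowSums(abs(off)) + u
  omega
}

#' Build a diagonally dominant precision matrix on a given graph support
#'
#' Off-diagonal entries are \code{alpha_ij} (drawn uniformly from \{-1, +1\})
#' where an edge is present within a group, \code{alpha_ij * vb} for edges
#' between groups, and zero elsewhere. The diagonal is set to the absolute
#' row sum plus \code{u > 0}, which makes the matrix strictly diagonally
#' dominant and hence positive definite.
#'
#' @param theta binary symmetric adjacency with zero diagonal.
#' @param groups optional integer/factor vector of length p assigning each
#'   node to a group (e.g. an OMICs platform); \code{NULL} for a single group.
#' @param vb scaling factor in [0, 1] applied to between-group edges.
#' @param u positive diagonal-dominance constant.
#' @param seed optional integer seed for the sign draws.
#' @param alpha optional pre-drawn symmetric sign matrix (used internally to
#'   share signs between u-tuning and the final build).
#' @return symmetric positive-definite precision matrix.
#' @export
#' @examples
#' theta <- matrix(0, 2, 2); theta[1, 2] <- theta[2, 1] <- 1
#' build_precision(theta, u = 0.1, seed = 1)
build_precision <- function(theta, groups = NULL, vb = 1, u = 0.1,
                            seed = NULL, alpha = NULL) {
  theta <- .check_matrix(theta, "theta")
  if (!.is_symmetric(theta) || any(diag(theta) != 0) ||
      !all(theta %in% c(0, 1))) {
    stop("'theta' must be a binary symmetric adjacency with zero diagonal")
  }
  p <- nrow(theta)
  if (!is.null(groups) && length(groups) != p) {
    stop("'groups' must have length p = ", p)
  }
  vb <- .check_prob(vb, "vb")
  if (!is.numeric(u) || length(u) != 1L || u <= 0) stop("'u' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(alpha)) alpha <- .draw_alpha(p)
  off <- .precision_offdiag(theta, alpha, groups, vb)
  omega <- .precision_with_u(off, u)
  dimnames(omega) <- dimnames(theta)
  omega
}

# symmetric matrix of independent uniform draws from {-1, +1}
.draw_alpha <- function(p) {
  a <- matrix(0, p, p)
  a[upper.tri(a)] <- sample(c(-1, 1), p * (p - 1) / 2, replace = TRUE)
  a + t(a)
}

#' Default tuning grid for the diagonal-dominance constant u
#'
#' @param size number of grid points.
#' @return increasing vector of 50 log-spaced values in [1e-5, 1e2].
#' @export
u_grid_default <- function(size = 50) {
  exp(seq(log(1e-5), log(1e2), length.out = size))
}

#' Tune the diagonal-dominance constant by contrast maximisation
#'
#' For each candidate \code{u}, the precision matrix is assembled on the same
#' support and signs, inverted, converted to a correlation matrix, and scored
#' by [contrast()]. The smallest \code{u} attaining the maximal contrast is
#' returned (ties favour smaller \code{u}, i.e. stronger partial
#' correlations).
#'
#' @inheritParams build_precision
#' @param u_grid increasing vector of positive candidate values.
#' @return the selected element of \code{u_grid}.
#' @export
tune_u <- function(theta, groups = NULL, vb = 1, u_grid = u_grid_default(),
                   seed = NULL, alpha = NULL) {
  if (length(u_grid) == 0L || any(u_grid <= 0)) {
    stop("'u_grid' must be a nonempty vector of positive values")
  }
  u_grid <- sort(u_grid)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(alpha)) alpha <- .draw_alpha(nrow(theta))
  off <- .precision_offdiag(theta, alpha, groups, vb)
  scores <- vapply(u_grid, function(u) {
    omega <- .precision_with_u(off, u)
    contrast(stats::cov2cor(solve(omega)))
  }, numeric(1))
  u_grid[which.max(scores)]
}

#' Simulate multivariate Normal data with a known conditional-independence
#' graph
#'
#' Composes the full generative model: a graph is drawn
#' ([simulate_adjacency()]), edge signs are drawn, the diagonal-dominance
#' constant \code{u} is tuned for maximal contrast ([tune_u()]) unless
#' supplied, the precision matrix is assembled ([build_precision()]), and
#' \code{n} rows are sampled from the centred multivariate Normal with
#' covariance equal to the inverse precision.
#'
#' @param n number of observations (>= 2).
#' @param p number of nodes.
#' @param nu graph density (random topology).
#' @param topology \code{"random"} or \code{"scale-free"}.
#' @param groups optional group labels of length p; when given, \code{vb}
#'   defaults to 0.2 so between-group entries are visibly weaker.
#' @param vb between-group scaling in [0, 1]; default 1 (no block effect)
#'   without groups, 0.2 with groups.
#' @param u optional fixed diagonal-dominance constant; tuned when
#'   \code{NULL}.
#' @param u_grid tuning grid for \code{u}.
#' @param seed integer seed driving every random draw (graph, signs,
#'   Normal sampling), making the dataset bit-reproducible.
#' @return an object of class \code{"graph_simulation"}: a list with the data
#'   \code{X} (n x p), adjacency \code{theta}, precision \code{omega},
#'   covariance \code{sigma}, and the generating parameters.
#' @export
#' @examples
#' sim <- simulate_graph_data(n = 50, p = 10, nu = 0.1, seed = 1)
#' sim
simulate_graph_data <- function(n, p = 100, nu = 0.02,
                                topology = c("random", "scale-free"),
                                groups = NULL, vb = NULL, u = NULL,
                                u_grid = u_grid_default(), seed = NULL) {
  n <- .check_count(n, min = 2L, what = "n")
  topology <- match.arg(topology)
  if (is.null(vb)) vb <- if (is.null(groups)) 1 else 0.2
  if (!is.null(seed)) set.seed(seed)

  theta <- simulate_adjacency(p, nu = nu, topology = topology)
  alpha <- .draw_alpha(p)
  if (is.null(u)) {
    u <- tune_u(theta, groups = groups, vb = vb, u_grid = u_grid,
                alpha = alpha)
  }
  omega <- build_precision(theta, groups = groups, vb = vb, u = u,
                           alpha = alpha)
  sigma <- solve(omega)
  sigma <- (sigma + t(sigma)) / 2
  x <- matrix(stats::rnorm(n * p), n, p) %*% chol(sigma)
  colnames(x) <- colnames(theta)

  structure(list(X = x, theta = theta, omega = omega, sigma = sigma,
                 n = n, p = p, nu = nu, topology = topology,
                 groups = groups, vb = vb, u = u, seed = seed),
            class = "graph_simulation")
}

#' @export
print.graph_simulation <- function(x, ...) {
  n_edges <- sum(x$theta[upper.tri(x$theta)])
  cat("Simulated Gaussian graphical model dataset\n")
  cat(sprintf("  n = %d observations, p = %d nodes, %s graph, %d edges\n",
              x$n, x$p, x$topology, n_edges))
  cat(sprintf("  u = %.3g, vb = %.3g%s\n", x$u, x$vb,
              if (is.null(x$groups)) "" else
                sprintf(", %d groups", length(unique(x$groups)))))
  invisible(x)
}

#' Simulate a linear regression dataset with sparse true effects
#'
#' Predictors are generated by [simulate_graph_data()] (or as independent
#' standard Normals when \code{predictor_config} is \code{NULL}, i.e. an
#' identity precision matrix). A support of \code{n_true} predictors is
#' chosen uniformly at random; effects are drawn uniformly from \{-1, +1\}
#' (\code{"binary"}) or from \eqn{[-1,-0.5] \cup [0.5,1]} (\code{"mixed"}).
#' The outcome is Normal around the linear predictor with noise standard
#' deviation \eqn{\sigma = \sqrt{(1 - R^2)/R^2 \cdot s^2}}, where \eqn{s^2}
#' is the variance of the realised linear predictor, so the expected
#' proportion of explained variance equals \code{r2_target}.
#'
#' @param n number of observations.
#' @param p number of predictors.
#' @param n_true number of predictors with nonzero effect (1..p).
#' @param effect_scheme \code{"mixed"} or \code{"binary"}.
#' @param r2_target expected proportion of explained variance, in (0, 1).
#' @param predictor_config \code{NULL} for independent predictors, or a list
#'   of arguments passed to [simulate_graph_data()] (e.g. \code{nu},
#'   \code{topology}, \code{vb}, \code{groups}) to generate correlated
#'   predictors.
#' @param seed integer seed.
#' @return an object of class \code{"regression_simulation"}: a list with
#'   \code{X}, \code{y}, the coefficient vector \code{beta}, the index set
#'   \code{support}, the noise level \code{sigma_noise}, and \code{s2}.
#' @export
#' @examples
#' sim <- simulate_regression_data(n = 100, p = 20, n_true = 5, seed = 1)
#' sim$support
simulate_regression_data <- function(n, p = 50, n_true = 10,
                                     effect_scheme = c("mixed", "binary"),
                                     r2_target = 0.7,
                                     predictor_config = NULL, seed = NULL) {
  n <- .check_count(n, min = 2L, what = "n")
  p <- .check_count(p, min = 1L, what = "p")
  n_true <- .check_count(n_true, min = 1L, what = "n_true")
  if (n_true > p) stop("'n_true' must be at most p")
  effect_scheme <- match.arg(effect_scheme)
  r2_target <- .check_prob(r2_target, "r2_target", open_lower = TRUE,
                           open_upper = TRUE)
  if (!is.null(seed)) set.seed(seed)

  if (is.null(predictor_config)) {
    x <- matrix(stats::rnorm(n * p), n, p)
    colnames(x) <- paste0("var", seq_len(p))
  } else {
    args <- c(list(n = n, p = p), predictor_config)
    x <- do.call(simulate_graph_data, args)$X
  }

  support <- sort(sample.int(p, n_true))
  beta <- numeric(p)
  beta[support] <- if (effect_scheme == "binary") {
    sample(c(-1, 1), n_true, replace = TRUE)
  } else {
    sample(c(-1, 1), n_true, replace = TRUE) * stats::runif(n_true, 0.5, 1)
  }

  xb <- as.vector(x %*% beta)
  s2 <- stats::var(xb)
  sigma <- sqrt((1 - r2_target) / r2_target * s2)
  y <- xb + stats::rnorm(n, 0, sigma)

  structure(list(X = x, y = y, beta = beta, support = support,
                 sigma_noise = sigma, r2_target = r2_target, s2 = s2,
                 effect_scheme = effect_scheme, n = n, p = p, seed = seed),
            class = "regression_simulation")
}

#' @export
print.regression_simulation <- function(x, ...) {
  cat("Simulated sparse linear regression dataset\n")
  cat(sprintf("  n = %d, p = %d, %d true effects (%s), target R2 = %.2f\n",
              x$n, x$p, length(x$support), x$effect_scheme, x$r2_target))
  cat(sprintf("  noise sd = %.3f (s2 = %.3f)\n", x$sigma_noise, x$s2))
  invisible(x)
}
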