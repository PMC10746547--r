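#' Graphical LASSO with scalar or elementwise penalties
#'
#' Estimates a sparse precision matrix by maximising the penalised Gaussian
#' log-likelihood
#' \deqn{\log\det(\Omega) - \mathrm{tr}(S\Omega) - \sum_{i \ne j}
#'   \Lambda_{ij} |\Omega_{ij}|}
#' by block coordinate descent over columns of the covariance estimate; each
#' column update is an l1-penalised quadratic programme with per-coordinate
#' penalties, so an arbitrary symmetric penalty matrix \eqn{\Lambda} is
#' supported (block-structured penalties in particular). The diagonal is not
#' penalised unless the supplied penalty matrix has a nonzero diagonal.
#'
#' @param S empirical covariance (or correlation) matrix, symmetric positive
#'   semi-definite.
#' @param penalty a nonnegative scalar \eqn{\lambda} (applied to all
#'   off-diagonal entries) or a symmetric nonnegative p x p penalty matrix.
#' @param tol convergence tolerance: the mean absolute change of the
#'   off-diagonal covariance estimate per sweep, relative to the mean
#'   absolute off-diagonal of \code{S}.
#' @param max_iter maximum number of full sweeps.
#' @param warm optional warm start: a previous fit on the same \code{S}
#'   (typically at a nearby penalty), as returned by this function.
#' @param penalize_diagonal when \code{penalty} is a scalar, also apply it
#'   to the diagonal (the convention of the common graphical LASSO
#'   implementations; it regularises the fit when \code{S} is rank
#'   deficient). Set \code{FALSE} to penalise off-diagonal entries only.
#'   Ignored for matrix penalties, whose diagonal is used as given.
#' @param trace_objective record the penalised log-likelihood after each
#'   sweep (costs one matrix inversion per sweep; off by default).
#' @return an object of class \code{"glasso_fit"}: list with the symmetrised
#'   precision estimate \code{Theta}, the logical edge \code{selection}
#'   vector over [edge_pairs()] order, the adjacency matrix
#'   \code{adjacency}, the objective value, the duality \code{gap}
#'   (\eqn{\mathrm{tr}(S\Theta) + \|\Lambda \circ \Theta\|_1 - p}), and
#'   internal state (\code{W}, \code{B}) reusable as a warm start.
#' @export
#' @examples
#' S <- cor(matrix(rnorm(200), 40, 5))
#' fit <- glasso_solve(S, penalty = 0.2)
#' fit$adjacency
glasso_solve <- function(S, penalty, tol = 1e-4, max_iter = 100,
                         warm = NULL, trace_objective = FALSE,
                         penalize_diagonal = FALSE) {
  S <- .check_matrix(S, "S")
  if (!.is_symmetric(S, tol = 1e-6)) stop("'S' must be symmetric")
  p <- nrow(S)
  if (any(diag(S) <= 0)) {
    stop("'S' has a non-positive diagonal entry (constant feature?) at index ",
         which(diag(S) <= 0)[1])
  }
  if (is.matrix(penalty)) {
    penalty <- .check_matrix(penalty, "penalty")
    if (!.is_symmetric(penalty) || any(penalty < 0) ||
        nrow(penalty) != p) {
      stop("'penalty' must be a symmetric nonnegative p x p matrix")
    }
  } else {
    if (length(penalty) != 1L || penalty < 0) {
      stop("'penalty' must be a nonnegative scalar or matrix")
    }
    lam <- penalty
    penalty <- matrix(lam, p, p)
    if (!penalize_diagonal) diag(penalty) <- 0
  }
  S <- (S + t(S)) / 2

  res <- .glasso_bcd(S, penalty, tol, as.integer(max_iter),
                     W0 = warm$W, B0 = warm$B,
                     trace_objective = trace_objective)
  theta_raw <- res$Theta
  if (any(!is.finite(theta_raw))) {
    stop("graphical LASSO broke down numerically (penalty too weak for a ",
         "rank-deficient covariance?)")
  }
  theta <- (theta_raw + t(theta_raw)) / 2
  dimnames(theta) <- dimnames(S)
  selection <- .edge_support(theta_raw)
  adjacency <- matrix(0L, p, p, dimnames = dimnames(S))
  adjacency[edge_pairs(p)[selection, , drop = FALSE]] <- 1L
  adjacency <- adjacency + t(adjacency)

  gap <- sum(S * theta) + sum(penalty * abs(theta)) - p
  objective <- as.numeric(determinant(theta, logarithm = TRUE)$modulus) -
    sum(S * theta) - sum(penalty * abs(theta))
  if (!res$converged) {
    warning(sprintf(
      "graphical LASSO did not converge in %d sweeps (duality gap %.3g)",
      max_iter, gap))
  }

  structure(list(Theta = theta, selection = selection,
                 adjacency = adjacency, objective = objective, gap = gap,
                 iterations = res$iterations, converged = res$converged,
                 objective_trace = res$objective_trace,
                 W = res$W, B = res$B, penalty = penalty),
            class = "glasso_fit")
}

#' @export
print.glasso_fit <- function(x, ...) {
  p <- nrow(x$Theta)
  cat(sprintf(
    "Graphical LASSO fit: p = %d, %d edges, objective %.4f, gap %.2e\n",
    p, sum(x$selection), x$objective, x$gap))
  invisible(x)
}

#' Penalty grid spanning empty to dense models
#'
#' Builds a decreasing log-spaced grid of penalty values specific to the
#' dataset. For the LASSO the grid starts at
#' \eqn{\lambda_{max} = \max_j |X_j^T y| / n} (computed on standardised
#' columns and a centred outcome), the smallest penalty with an empty model,
#' and ends at \code{lambda_min_ratio} times it. For the graphical LASSO the
#' grid starts at the largest absolute off-diagonal of the correlation
#' matrix (empty graph) and ends at the largest penalty whose full-data fit
#' reaches at least \code{target_density} of the possible edges (located by
#' bisection on the log scale).
#'
#' @param x data matrix (n x p).
#' @param y outcome vector (LASSO only).
#' @param algorithm \code{"lasso"} or \code{"glasso"}.
#' @param family \code{"gaussian"} or \code{"binomial"} (LASSO only).
#' @param size number of grid values (>= 2), default 50.
#' @param lambda_min_ratio smallest grid value as a fraction of the largest
#'   (LASSO); default 0.01.
#' @param target_density edge density the densest visited graphical model
#'   should reach, default 0.5.
#' @param tol,max_iter solver controls for the bisection fits (glasso).
#' @return an object of class \code{"lambda_grid"}: list with strictly
#'   decreasing \code{values} and the construction details.
#' @export
make_lambda_grid <- function(x, y = NULL,
                             algorithm = c("lasso", "glasso"),
                             family = c("gaussian", "binomial"),
                             size = 50, lambda_min_ratio = 0.01,
                             target_density = 0.5,
                             tol = 1e-4, max_iter = 100) {
  algorithm <- match.arg(algorithm)
  family <- match.arg(family)
  size <- .check_count(size, min = 2L, what = "size")
  x <- .check_matrix(x, "x")
  n <- nrow(x)

  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature(s) at index ",
         paste(which(sds == 0), collapse = ", "),
         ": penalty grid undefined")
  }

  if (algorithm == "lasso") {
    if (is.null(y)) stop("'y' is required for the lasso")
    # 1/n variance in the standardisation, matching the convention of the
    # path solver, so the largest grid value is exactly the empty-model
    # threshold
    xs <- scale(x) * sqrt(n / (n - 1))
    r <- y - mean(y)
    lambda_max <- max(abs(crossprod(xs, r))) / n
    if (lambda_max < .Machine$double.eps^0.5) {
      stop("outcome is orthogonal to all features: lambda_max = 0")
    }
    values <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = size))
    details <- list(lambda_max = lambda_max,
                    lambda_min_ratio = lambda_min_ratio)
  } else {
    S <- stats::cor(x)
    lambda_max <- max(abs(S[upper.tri(S)]))
    n_edges <- ncol(x) * (ncol(x) - 1) / 2
    density_at <- function(lam, warm = NULL) {
      tryCatch({
        fit <- glasso_solve(S, lam, tol = tol, max_iter = max_iter,
                            warm = warm)
        list(density = sum(fit$selection) / n_edges, fit = fit)
      }, error = function(e) NULL)
    }
    # bracket: walk down by factor 2 until dense enough; a solver breakdown
    # (possible at weak penalties on rank-deficient covariances) caps the
    # grid at the last stable penalty
    hi <- lambda_max
    lo <- lambda_max / 2
    warm <- NULL
    lo_density <- 0
    for (step in 1:20) {
      d <- density_at(lo, warm)
      if (is.null(d)) {
        lo <- hi
        break
      }
      warm <- d$fit
      lo_density <- d$density
      if (lo_density >= target_density) break
      hi <- lo
      lo <- lo / 2
    }
    if (lo_density >= target_density) {
      # bisection on the log scale for the LARGEST lambda reaching the target
      for (step in 1:8) {
        mid <- sqrt(lo * hi)
        d <- density_at(mid, warm)
        if (is.null(d)) break
        warm <- d$fit
        if (d$density >= target_density) lo <- mid else hi <- mid
      }
    }
    lambda_min <- lo
    values <- exp(seq(log(lambda_max), log(lambda_min), length.out = size))
    details <- list(lambda_max = lambda_max, lambda_min = lambda_min,
                    density_at_min = lo_density,
                    target_density = target_density)
  }
  structure(list(values = values, algorithm = algorithm, family = family,
                 details = details),
            class = "lambda_grid")
}

#' @export
print.lambda_grid <- function(x, ...) {
  cat(sprintf("Penalty grid (%s): %d values from %.4g down to %.4g\n",
              x$algorithm, length(x$values), max(x$values), min(x$values)))
  invisible(x)
}

# accept either a lambda_grid or a plain decreasing numeric vector
.grid_values <- function(lambda) {
  v <- if (inherits(lambda, "lambda_grid")) lambda$values else as.numeric(lambda)
  if (length(v) < 1L) stop("'lambda' is empty")
  if (length(v) > 1L && any(diff(v) >= 0)) {
    stop("'lambda' values must be strictly decreasing")
  }
  if (any(v < 0)) stop("'lambda' values must be nonnegative")
  v
}

#' LASSO selection status along a penalty grid
#'
#' Fits the l1-penalised regression path (via \pkg{glmnet}) and reports, for
#' every feature and every grid value, whether its coefficient is nonzero.
#' Columns of \code{x} are standardised internally; the intercept is
#' unpenalised and never reported as a feature.
#'
#' @param x predictor matrix (n x p).
#' @param y outcome: numeric (gaussian) or binary (binomial).
#' @param lambda a [make_lambda_grid()] object or a decreasing numeric
#'   vector of penalties.
#' @param family \code{"gaussian"} or \code{"binomial"}.
#' @return binary matrix (p features x L grid values); entry (j, l) is 1
#'   iff feature j has a nonzero coefficient at the l-th penalty.
#' @export
lasso_select <- function(x, y, lambda,
                         family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  x <- .check_matrix(x, "x")
  if (anyNA(y)) stop("'y' contains missing values")
  if (nrow(x) < 2L) stop("at least 2 observations are required")
  if (length(y) != nrow(x)) stop("'x' and 'y' are not row-aligned")
  values <- .grid_values(lambda)

  fit <- glmnet::glmnet(x, y, family = family, lambda = values,
                        standardize = TRUE, intercept = TRUE)
  beta <- as.matrix(fit$beta)
  out <- matrix(0L, ncol(x), length(values),
                dimnames = list(colnames(x), signif(values, 6)))
  # glmnet can stop the path early; match fitted lambdas back to the grid
  idx <- vapply(fit$lambda, function(l) which.min(abs(values - l)),
                integer(1))
  out[, idx] <- (abs(beta) > 1e-8) * 1L
  if (length(fit$lambda) < length(values)) {
    # unvisited (smaller) penalties inherit the last fitted pattern
    last <- max(idx)
    if (last < length(values)) {
      out[, (last + 1):length(values)] <- out[, last]
    }
  }
  out
}
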