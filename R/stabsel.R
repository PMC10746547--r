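#' Stability selection with automated calibration
#'
#' Fits a stability selection model around the LASSO (variable selection
#' against an outcome) or the graphical LASSO (edge selection in a Gaussian
#' graphical model). The base selector is run on \code{K} resamples of the
#' data over a grid of penalties spanning empty to dense models; selection
#' proportions are computed per feature (or edge) and penalty; and the
#' penalty \eqn{\lambda} and the threshold in selection proportion \eqn{\pi}
#' are calibrated jointly by maximising the stability score, optionally
#' under a constraint on a closed-form upper bound of the per-family error
#' rate (PFER). The stable set is the set of features with selection
#' proportion at least \eqn{\hat\pi} at \eqn{\hat\lambda}.
#'
#' @param x data matrix (n observations x p features).
#' @param y outcome vector for the LASSO; \code{NULL} for the graphical
#'   LASSO.
#' @param algorithm base selector: \code{"lasso"} or \code{"glasso"};
#'   \code{"auto"} picks the LASSO when \code{y} is given.
#' @param family GLM family for the LASSO (\code{"gaussian"} or
#'   \code{"binomial"}).
#' @param K number of resampling units (default 100).
#' @param scheme resampling scheme, see [draw_resamples()].
#' @param fraction subsample fraction (default 0.5).
#' @param lambda penalty grid: \code{NULL} to build a dataset-specific grid
#'   with [make_lambda_grid()], a \code{lambda_grid} object, or a decreasing
#'   numeric vector.
#' @param n_lambda grid size when the grid is built internally.
#' @param pi_grid thresholds in selection proportion (default 31 values in
#'   [0.6, 0.9]).
#' @param pfer PFER bound used as calibration constraint: \code{"none"},
#'   \code{"mb"} or \code{"ss"}.
#' @param eta PFER budget when constrained.
#' @param two_categories see [stability_score()].
#' @param tol,max_iter graphical LASSO solver controls.
#' @param seed integer seed driving the resampling.
#' @return an object of class \code{"stabsel"} (and \code{"stabsel_glasso"}
#'   for graphical models): list with the calibration (\code{lambda_hat},
#'   \code{pi_hat}, \code{score_max}), the selection \code{proportions} at
#'   the calibrated penalty, the logical \code{stable} vector, the full
#'   \code{counts} and score \code{surface}, and the calibration details.
#' @seealso [stabsel_multiblock()] for graphical models with known feature
#'   groups; [selection_performance()] to score a fit against a known truth.
#' @export
#' @examples
#' sim <- simulate_regression_data(n = 80, p = 20, n_true = 4, seed = 1)
#' fit <- stabsel(sim$X, sim$y, K = 20, n_lambda = 15, seed = 1)
#' fit
#' stable_set(fit)
stabsel <- function(x, y = NULL,
                    algorithm = c("auto", "lasso", "glasso"),
                    family = c("gaussian", "binomial"),
                    K = 100,
                    scheme = c("subsample", "bootstrap", "cpss"),
                    fraction = 0.5,
                    lambda = NULL, n_lambda = 50,
                    pi_grid = pi_grid_default(),
                    pfer = c("none", "mb", "ss"), eta = Inf,
                    two_categories = FALSE,
                    tol = 1e-3, max_iter = 100, seed = NULL) {
  algorithm <- match.arg(algorithm)
  family <- match.arg(family)
  scheme <- match.arg(scheme)
  pfer <- match.arg(pfer)
  x <- .check_matrix(x, "x")
  if (algorithm == "auto") algorithm <- if (is.null(y)) "glasso" else "lasso"

  if (is.null(lambda)) {
    lambda <- make_lambda_grid(x, y, algorithm = algorithm, family = family,
                               size = n_lambda, tol = tol,
                               max_iter = max_iter)
  }
  counts <- selection_counts(x, y, algorithm = algorithm, lambda = lambda,
                             K = K, scheme = scheme, fraction = fraction,
                             family = family, tol = tol,
                             max_iter = max_iter, seed = seed)
  surface <- score_surface(counts, pi_grid = pi_grid,
                           two_categories = two_categories)
  cal <- calibrate_surface(surface, pfer = pfer, eta = eta)

  proportions <- counts$H[, cal$lambda_index] / K
  stable <- proportions >= cal$pi_hat - .EPS

  out <- structure(list(call = match.call(),
                        algorithm = algorithm, family = family,
                        p = counts$p, N = counts$N, n = counts$n,
                        K = K, scheme = scheme, fraction = fraction,
                        lambda = counts$lambda, pi_grid = pi_grid,
                        counts = counts, surface = surface,
                        calibration = cal,
                        lambda_hat = cal$lambda_hat, pi_hat = cal$pi_hat,
                        score_max = cal$score_max,
                        proportions = proportions, stable = stable,
                        edges = counts$edges, seed = seed),
                   class = "stabsel")
  if (algorithm == "glasso") class(out) <- c("stabsel_glasso", "stabsel")
  out
}

#' @export
print.stabsel <- function(x, ...) {
  cat(sprintf("Stability selection %s (%s, K = %d)\n",
              if (x$algorithm == "glasso") "graphical LASSO" else "LASSO",
              x$scheme, x$K))
  cat(sprintf(
    "  grid: %d penalties x %d thresholds; calibrated lambda = %.4g, pi = %.2f\n",
    length(x$lambda), length(x$pi_grid), x$lambda_hat, x$pi_hat))
  cat(sprintf("  stability score %.2f; %d of %d %s stable\n",
              x$score_max, sum(x$stable), x$N,
              if (x$algorithm == "glasso") "edges" else "features"))
  if (!is.null(x$calibration$bound)) {
    cat(sprintf("  constrained: PFER_%s = %.3f <= %g\n",
                toupper(x$calibration$pfer), x$calibration$bound,
                x$calibration$eta))
  }
  invisible(x)
}

#' @export
summary.stabsel <- function(object, ...) {
  print(object)
  top <- sort(object$proportions, decreasing = TRUE)
  top <- top[top > 0]
  cat("\nTop selection proportions at the calibrated penalty:\n")
  print(utils::head(round(top, 3), 10))
  invisible(object)
}

#' Selection proportions of a stability selection fit
#'
#' @param object a [stabsel()] fit.
#' @param ... unused.
#' @return named vector of selection proportions at the calibrated penalty.
#' @export
coef.stabsel <- function(object, ...) {
  object$proportions
}

#' Stable feature or edge set
#'
#' @param object a [stabsel()] fit.
#' @return for the LASSO, the names (or indices) of stably selected
#'   features; for the graphical LASSO, a two-column matrix of stably
#'   selected node pairs.
#' @export
stable_set <- function(object) {
  UseMethod("stable_set")
}

#' @export
stable_set.stabsel <- function(object) {
  which(object$stable)
}

#' @export
stable_set.stabsel_glasso <- function(object) {
  object$edges[object$stable, , drop = FALSE]
}

#' Adjacency matrix of the calibrated graph
#'
#' @param object a graphical [stabsel()] fit.
#' @return symmetric 0/1 adjacency matrix of stably selected edges.
#' @export
stable_graph <- function(object) {
  stopifnot(inherits(object, "stabsel_glasso"))
  adj <- matrix(0L, object$p, object$p)
  adj[object$edges[object$stable, , drop = FALSE]] <- 1L
  adj + t(adj)
}

#' Calibration heatmap of a stability selection fit
#'
#' Displays the stability score over the (lambda, pi) grid with the
#' calibrated pair marked; cells excluded by a PFER constraint are blanked.
#'
#' @param x a [stabsel()] fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.stabsel <- function(x, ...) {
  sc <- x$surface$score
  cal <- x$calibration
  if (cal$pfer != "none") {
    bound <- switch(cal$pfer, mb = x$surface$pfer_mb, ss = x$surface$pfer_ss)
    sc[bound > cal$eta] <- NA
  }
  graphics::image(x = seq_along(x$lambda), y = x$pi_grid, z = sc,
                  xlab = expression(lambda ~ "(grid index, decreasing)"),
                  ylab = expression(pi),
                  main = "Stability score", ...)
  graphics::points(cal$lambda_index, cal$pi_hat, pch = 4, cex = 2, lwd = 2)
  invisible(x)
}

#' Export a calibrated fit as JSON
#'
#' Writes the calibrated parameters, maximal score, PFER bound and stable
#' set to a JSON file.
#'
#' @param object a [stabsel()] fit.
#' @param path output file.
#' @export
write_calibration_json <- function(object, path) {
  stopifnot(inherits(object, "stabsel"))
  stable <- if (inherits(object, "stabsel_glasso")) {
    ep <- stable_set(object)
    data.frame(node1 = ep[, 1], node2 = ep[, 2])
  } else {
    names(object$proportions)[object$stable]
  }
  out <- list(algorithm = object$algorithm,
              lambda_hat = object$lambda_hat, pi_hat = object$pi_hat,
              score_max = object$score_max,
              pfer = object$calibration$pfer,
              eta = object$calibration$eta,
              bound = object$calibration$bound,
              n_stable = sum(object$stable),
              stable_set = stable)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export selection proportions as CSV
#'
#' @param object a [stabsel()] fit.
#' @param path output file.
#' @export
write_proportions <- function(object, path) {
  stopifnot(inherits(object, "stabsel"))
  if (inherits(object, "stabsel_glasso")) {
    df <- data.frame(node1 = object$edges[, 1], node2 = object$edges[, 2],
                     feature = names(object$proportions),
                     selection_proportion = object$proportions,
                     stable = as.integer(object$stable))
  } else {
    df <- data.frame(feature = names(object$proportions),
                     selection_proportion = object$proportions,
                     stable = as.integer(object$stable))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
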