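#' Draw resampling index sets
#'
#' @param n number of observations (>= 4).
#' @param K number of resampling units: subsamples, bootstrap samples, or
#'   complementary pairs (for \code{"cpss"}, K pairs means 2K model fits).
#' @param scheme \code{"subsample"} (without replacement),
#'   \code{"bootstrap"} (with replacement, size n), or \code{"cpss"}
#'   (complementary pairs: each unit is a random permutation of the
#'   observations split into two disjoint halves).
#' @param fraction subsample size as a fraction of n (subsample scheme).
#' @param seed optional integer seed.
#' @return a list of K integer index vectors, or for \code{"cpss"} a list of
#'   K lists with elements \code{a} and \code{b} (the two halves).
#' @export
draw_resamples <- function(n, K = 100,
                           scheme = c("subsample", "bootstrap", "cpss"),
                           fraction = 0.5, seed = NULL) {
  n <- .check_count(n, min = 4L, what = "n")
  K <- .check_count(K, min = 1L, what = "K")
  scheme <- match.arg(scheme)
  fraction <- .check_prob(fraction, "fraction", open_lower = TRUE,
                          open_upper = TRUE)
  m <- floor(fraction * n)
  if (m < 2L) stop("subsample size fraction * n must be at least 2")
  if (!is.null(seed)) set.seed(seed)

  out <- switch(scheme,
    subsample = replicate(K, sort(sample.int(n, m)), simplify = FALSE),
    bootstrap = replicate(K, sample.int(n, n, replace = TRUE),
                          simplify = FALSE),
    cpss = replicate(K, {
      perm <- sample.int(n)
      h <- floor(n / 2)
      list(a = sort(perm[seq_len(h)]), b = sort(perm[(h + 1):n]))
    }, simplify = FALSE)
  )
  attr(out, "scheme") <- scheme
  out
}

# selection pattern (features/edges x lambda) for one data subset
.fit_pattern <- function(x, y, algorithm, values, family, tol, max_iter) {
  if (algorithm == "lasso") {
    lasso_select(x, y, values, family = family) > 0L
  } else {
    S <- stats::cor(x)
    p <- ncol(x)
    sel <- matrix(FALSE, p * (p - 1) / 2, length(values))
    warm <- NULL
    for (l in seq_along(values)) {
      fit <- glasso_solve(S, values[l], tol = tol, max_iter = max_iter,
                          warm = warm)
      warm <- fit
      sel[, l] <- fit$selection
    }
    sel
  }
}

#' Selection counts across resampled model fits
#'
#' Runs the base selector (LASSO or graphical LASSO) on K resamples of the
#' data for every penalty in the grid and counts, per feature (or edge) and
#' penalty, the number of resamples in which it was selected. Under the
#' CPSS scheme a feature counts as selected only if it is selected in both
#' halves of a complementary pair. Columns of the data are standardised
#' within each resample (the graphical LASSO is fitted on the resample's
#' correlation matrix).
#'
#' @inheritParams draw_resamples
#' @param x data matrix (n x p).
#' @param y outcome vector (LASSO) or \code{NULL} (graphical LASSO).
#' @param algorithm \code{"lasso"} or \code{"glasso"}.
#' @param lambda a [make_lambda_grid()] object or decreasing numeric vector.
#' @param family GLM family for the LASSO.
#' @param tol,max_iter graphical LASSO solver controls.
#' @return an object of class \code{"selection_counts"}: list with the
#'   integer count matrix \code{H} (N features-or-edges x L penalties, each
#'   entry in 0..K), \code{K}, the penalty values, and bookkeeping fields
#'   (\code{N}, \code{p}, \code{algorithm}, edge pairs for graphical
#'   models).
#' @export
selection_counts <- function(x, y = NULL,
                             algorithm = c("lasso", "glasso"),
                             lambda, K = 100,
                             scheme = c("subsample", "bootstrap", "cpss"),
                             fraction = 0.5,
                             family = c("gaussian", "binomial"),
                             tol = 1e-3, max_iter = 100, seed = NULL) {
  algorithm <- match.arg(algorithm)
  scheme <- match.arg(scheme)
  family <- match.arg(family)
  x <- .check_matrix(x, "x")
  values <- .grid_values(lambda)
  n <- nrow(x)
  p <- ncol(x)
  N <- if (algorithm == "glasso") p * (p - 1) / 2 else p
  if (algorithm == "lasso" && is.null(y)) stop("'y' is required for the lasso")

  resamples <- draw_resamples(n, K = K, scheme = scheme,
                              fraction = fraction, seed = seed)
  H <- matrix(0L, N, length(values))
  for (k in seq_len(K)) {
    r <- resamples[[k]]
    sel <- tryCatch({
      if (scheme == "cpss") {
        sa <- .fit_pattern(x[r$a, , drop = FALSE], y[r$a], algorithm,
                           values, family, tol, max_iter)
        sb <- .fit_pattern(x[r$b, , drop = FALSE], y[r$b], algorithm,
                           values, family, tol, max_iter)
        sa & sb
      } else {
        .fit_pattern(x[r, , drop = FALSE], y[r], algorithm,
                     values, family, tol, max_iter)
      }
    }, error = function(e) {
      stop(sprintf("selector failed on resample %d: %s", k,
                   conditionMessage(e)), call. = FALSE)
    })
    H <- H + sel
  }

  feature_names <- if (algorithm == "glasso") {
    ep <- edge_pairs(p)
    nm <- colnames(x)
    if (is.null(nm)) nm <- paste0("var", seq_len(p))
    paste(nm[ep[, 1]], nm[ep[, 2]], sep = ":")
  } else {
    nm <- colnames(x)
    if (is.null(nm)) paste0("var", seq_len(p)) else nm
  }
  rownames(H) <- feature_names
  colnames(H) <- signif(values, 6)

  structure(list(H = H, K = K, lambda = values, scheme = scheme,
                 fraction = fraction, N = N, p = p, n = n,
                 algorithm = algorithm, family = family, seed = seed,
                 edges = if (algorithm == "glasso") edge_pairs(p) else NULL),
            class = "selection_counts")
}

#' @export
print.selection_counts <- function(x, ...) {
  cat(sprintf(
    "Selection counts: %d %s x %d penalties, K = %d (%s%s)\n",
    x$N, if (x$algorithm == "glasso") "edges" else "features",
    length(x$lambda), x$K, x$scheme,
    if (x$scheme == "subsample")
      sprintf(", fraction %.2f", x$fraction) else ""))
  invisible(x)
}

#' Export selection counts or proportions as CSV
#'
#' Rows are features (or edges, named \code{node1:node2}), columns are
#' penalty values.
#'
#' @param counts a [selection_counts()] object.
#' @param path output file.
#' @param proportions write proportions H/K instead of raw counts.
#' @export
write_selection_counts <- function(counts, path, proportions = FALSE) {
  stopifnot(inherits(counts, "selection_counts"))
  m <- if (proportions) counts$H / counts$K else counts$H
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
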