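# Floating-point guard for category boundaries: K*pi computed in double can
# land a hair above or below the intended integer (e.g. 50 * 0.62).
.EPS <- 1e-9

#' Average model size q
#'
#' Mean number of selected features across the K resampled fits at one
#' penalty, rounded half-up: \eqn{q = \lfloor \sum_j H(j)/K + 1/2 \rfloor}.
#'
#' @param h integer vector of selection counts (one penalty), entries in
#'   0..K.
#' @param K number of resampling units.
#' @return integer model size.
#' @export
#' @examples
#' model_size_q(c(100, 100, 50), K = 100) # mean size 2.5, rounds half-up to 3
model_size_q <- function(h, K) {
  if (any(h < 0) || any(h > K)) stop("counts must lie in [0, K]")
  as.integer(floor(sum(h) / K + 0.5))
}

# log binomial category probabilities under the equiprobable-selection
# null: log P(stably selected), log P(unstable), log P(stably excluded) for
# H ~ B(K, gamma), with the CDF evaluated at ceiling(K*pi) - 1 and
# floor(K*(1-pi)). Tail probabilities at sparse models underflow double
# precision, so everything stays on the log scale.
.category_logprobs <- function(K, gamma, pi) {
  c_hi <- ceiling(K * pi - .EPS) - 1
  c_lo <- floor(K * (1 - pi) + .EPS)
  log_sel <- stats::pbinom(c_hi, K, gamma, lower.tail = FALSE, log.p = TRUE)
  log_exc <- stats::pbinom(c_lo, K, gamma, log.p = TRUE)
  p_unst <- 1 - exp(log_sel) - exp(log_exc)
  log_unst <- if (p_unst > 1e-12) {
    log(p_unst)
  } else if (c_lo + 1 <= c_hi) {
    # both tails carry almost all mass: sum the middle on the log scale
    m <- stats::dbinom((c_lo + 1):c_hi, K, gamma, log = TRUE)
    mmax <- max(m)
    if (is.finite(mmax)) mmax + log(sum(exp(m - mmax))) else -Inf
  } else {
    -Inf
  }
  c(sel = log_sel, unstable = log_unst, exc = log_exc)
}

# category counts for a vector of selection counts
.category_counts <- function(h, K, pi) {
  n_sel <- sum(h >= K * pi - .EPS)
  n_exc <- sum(h <= K * (1 - pi) + .EPS)
  c(sel = n_sel, unstable = length(h) - n_sel - n_exc, exc = n_exc)
}

#' Stability score at one (lambda, pi) pair
#'
#' Features are classified from their selection counts as stably selected
#' (\eqn{H \ge K\pi}), stably excluded (\eqn{H \le K(1-\pi)}) or unstable.
#' Under the null hypothesis of maximally unstable selection, every feature
#' is selected independently with probability \eqn{\gamma = q/N}, so the
#' counts are Binomial(K, \eqn{\gamma}) and each category has a closed-form
#' probability. The score is the negative log-likelihood of the observed
#' classification under this null: high scores flag classifications that are
#' very unlikely under instability, i.e. stable models. Empty and saturated
#' models (and degenerate nulls assigning probability zero to an observed
#' category) score 0, so the score is only informative between those
#' extremes.
#'
#' @param h selection counts at one penalty (entries in 0..K).
#' @param K number of resampling units.
#' @param pi threshold in selection proportion, in (0.5, 1).
#' @param N total number of features (defaults to \code{length(h)}).
#' @param two_categories collapse the classification to stably selected vs
#'   not stably selected (ignoring the information in stable exclusions).
#'   Off by default, as discarding stable exclusions can hamper selection
#'   performance.
#' @return nonnegative score (0 for degenerate cases).
#' @export
#' @examples
#' stability_score(c(10, 0), K = 10, pi = 0.8) # -log((56/1024)^2)
stability_score <- function(h, K, pi, N = length(h),
                            two_categories = FALSE) {
  pi <- .check_prob(pi, "pi")
  if (pi <= 0.5 || pi >= 1) stop("'pi' must lie in (0.5, 1)")
  if (any(h < 0) || any(h > K)) stop("counts must lie in [0, K]")
  q <- model_size_q(h, K)
  gamma <- q / N
  .score_with_gamma(h, K, pi, gamma, two_categories = two_categories)
}

#' Martin-Boulesteix-style PFER upper bound
#'
#' Closed-form upper bound on the per-family error rate (expected number of
#' falsely selected features) of a stability selection model with average
#' model size q, threshold pi and N candidate features:
#' \eqn{q^2 / ((2\pi - 1) N)}. Valid under exchangeability of selected
#' features (or under CPSS resampling without it).
#'
#' @param q average model size (per penalty).
#' @param pi threshold(s) in selection proportion, > 0.5.
#' @param N number of candidate features or edges.
#' @return bound value(s), vectorised over \code{q} and \code{pi}.
#' @export
#' @examples
#' pfer_mb(q = 10, pi = 0.75, N = 100) # 2
pfer_mb <- function(q, pi, N) {
  if (any(pi <= 0.5)) stop("'pi' must be greater than 0.5")
  if (any(q < 0) || N < 1) stop("'q' must be >= 0 and 'N' >= 1")
  q^2 / ((2 * pi - 1) * N)
}

#' Shah-Samworth-style PFER upper bound
#'
#' Stricter two-branch upper bound on the expected number of low
#' selection-probability features, valid under unimodality of the
#' distribution of selection proportions obtained with complementary-pairs
#' resampling:
#' \deqn{\frac{1}{2(2\pi - 1 - 1/K)} \frac{q^2}{N} \quad (\pi \le 0.75),
#'   \qquad \frac{4(1 - \pi + 1/K)}{1 + 2/K} \frac{q^2}{N} \quad (\pi >
#'   0.75).}
#'
#' @inheritParams pfer_mb
#' @param K number of resampling units (complementary pairs under CPSS).
#' @return bound value(s), vectorised over \code{q} and \code{pi}.
#' @export
#' @examples
#' pfer_ss(q = 10, pi = 0.9, N = 100, K = 100) # 4 * 0.11 / 1.02
pfer_ss <- function(q, pi, N, K) {
  if (any(pi <= 0.5)) stop("'pi' must be greater than 0.5")
  K <- .check_count(K, min = 2L, what = "K")
  low <- pi <= 0.75
  if (any(low & (2 * pi - 1 - 1 / K) <= 0)) {
    stop("denominator 2*pi - 1 - 1/K is not positive; increase K or pi")
  }
  out <- ifelse(low,
                q^2 / (2 * (2 * pi - 1 - 1 / K) * N),
                4 * (1 - pi + 1 / K) / (1 + 2 / K) * q^2 / N)
  out
}

#' Default grid of thresholds in selection proportion
#'
#' @param from,to,length.out grid range and size; defaults give 31 values
#'   between 0.6 and 0.9.
#' @return increasing numeric vector in (0.5, 1).
#' @export
pi_grid_default <- function(from = 0.6, to = 0.9, length.out = 31) {
  seq(from, to, length.out = length.out)
}

#' Stability score surface over the (lambda, pi) grid
#'
#' Evaluates the stability score, the average model size q, the null
#' selection probability gamma = q/N and both PFER upper bounds at every
#' pair of penalty and threshold values.
#'
#' @param counts a [selection_counts()] object (or a bare count matrix with
#'   \code{K} supplied).
#' @param pi_grid thresholds in selection proportion, all in (0.5, 1).
#' @param K number of resampling units (only when \code{counts} is a bare
#'   matrix).
#' @param two_categories see [stability_score()].
#' @return an object of class \code{"stability_surface"}: list with the
#'   score matrix (L x P), \code{q} and \code{gamma} per penalty,
#'   \code{pfer_mb} and \code{pfer_ss} matrices, the grids, and \code{N}.
#' @export
score_surface <- function(counts, pi_grid = pi_grid_default(), K = NULL,
                          two_categories = FALSE) {
  if (inherits(counts, "selection_counts")) {
    H <- counts$H
    K <- counts$K
    lambda <- counts$lambda
  } else {
    H <- as.matrix(counts)
    if (is.null(K)) stop("'K' is required when 'counts' is a bare matrix")
    lambda <- as.numeric(colnames(H))
    if (anyNA(lambda)) lambda <- seq_len(ncol(H))
  }
  if (any(pi_grid <= 0.5) || any(pi_grid >= 1)) {
    stop("'pi_grid' values must lie in (0.5, 1)")
  }
  N <- nrow(H)
  L <- ncol(H)
  P <- length(pi_grid)

  q <- vapply(seq_len(L), function(l) model_size_q(H[, l], K), integer(1))
  gamma <- q / N
  score <- matrix(0, L, P)
  for (l in seq_len(L)) {
    for (m in seq_len(P)) {
      score[l, m] <- stability_score(H[, l], K, pi_grid[m], N = N,
                                     two_categories = two_categories)
    }
  }
  mb <- outer(q, pi_grid, function(qq, pp) pfer_mb(qq, pp, N))
  ss <- outer(q, pi_grid, function(qq, pp) pfer_ss(qq, pp, N, K))
  dimnames(score) <- dimnames(mb) <- dimnames(ss) <-
    list(signif(lambda, 6), signif(pi_grid, 6))

  structure(list(score = score, q = q, gamma = gamma,
                 pfer_mb = mb, pfer_ss = ss,
                 lambda = lambda, pi_grid = pi_grid, K = K, N = N,
                 two_categories = two_categories),
            class = "stability_surface")
}

#' @export
print.stability_surface <- function(x, ...) {
  cat(sprintf(
    "Stability score surface: %d penalties x %d thresholds (N = %d, K = %d)\n",
    length(x$lambda), length(x$pi_grid), x$N, x$K))
  cat(sprintf("  max score %.2f\n", max(x$score)))
  invisible(x)
}

#' Export a stability score surface as CSV
#'
#' @param surface a [score_surface()] object.
#' @param path output file; rows are penalties, columns thresholds.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "stability_surface"))
  utils::write.csv(as.data.frame(surface$score), path, row.names = TRUE)
  invisible(path)
}

#' Calibrate (lambda, pi) by maximising the stability score
#'
#' Unconstrained calibration returns the grid pair with the highest score;
#' constrained calibration restricts the search to pairs whose PFER upper
#' bound does not exceed \code{eta} (pairs violating the bound are never
#' evaluated as candidate models). Ties are broken toward the largest
#' penalty (sparsest model), then the largest threshold.
#'
#' @param surface a [score_surface()] object.
#' @param pfer \code{"none"}, \code{"mb"} or \code{"ss"}: which bound to
#'   constrain, if any.
#' @param eta PFER budget (> 0); \code{Inf} makes the constraint vacuous.
#' @return an object of class \code{"stability_calibration"}: list with
#'   \code{lambda_hat}, \code{pi_hat}, their grid indices, the maximal
#'   score, and the bound value at the optimum.
#' @export
calibrate_surface <- function(surface, pfer = c("none", "mb", "ss"),
                              eta = Inf) {
  stopifnot(inherits(surface, "stability_surface"))
  pfer <- match.arg(pfer)
  if (pfer != "none" && (!is.numeric(eta) || eta <= 0)) {
    stop("'eta' must be a positive PFER budget")
  }
  bound <- switch(pfer, none = NULL, mb = surface$pfer_mb,
                  ss = surface$pfer_ss)
  feasible <- if (is.null(bound)) {
    matrix(TRUE, nrow(surface$score), ncol(surface$score))
  } else {
    bound <= eta
  }
  if (!any(feasible)) {
    stop(sprintf(
      "no (lambda, pi) pair satisfies PFER_%s <= %g (minimum achievable: %.4g)",
      toupper(pfer), eta, min(bound)))
  }
  sc <- surface$score
  sc[!feasible] <- -Inf
  best <- max(sc)
  cand <- which(sc == best, arr.ind = TRUE)
  # lambda grid is stored in decreasing order: smallest row index = largest
  # lambda; prefer it, then the largest pi (largest column index)
  cand <- cand[order(cand[, 1], -cand[, 2]), , drop = FALSE]
  l <- cand[1, 1]
  m <- cand[1, 2]

  structure(list(lambda_hat = surface$lambda[l],
                 pi_hat = surface$pi_grid[m],
                 lambda_index = l, pi_index = m,
                 score_max = surface$score[l, m],
                 q = surface$q[l],
                 pfer = pfer, eta = if (pfer == "none") NULL else eta,
                 bound = if (is.null(bound)) NULL else bound[l, m]),
            class = "stability_calibration")
}

#' @export
print.stability_calibration <- function(x, ...) {
  cat(sprintf(
    "Calibrated stability selection: lambda = %.4g, pi = %.2f (score %.2f)\n",
    x$lambda_hat, x$pi_hat, x$score_max))
  if (!is.null(x$bound)) {
    cat(sprintf("  PFER_%s bound %.3f <= eta = %g\n", toupper(x$pfer),
                x$bound, x$eta))
  }
  invisible(x)
}
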