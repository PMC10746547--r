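#' Selection performance against a known truth
#'
#' Counts true positives, false positives and false negatives of a selected
#' feature (or edge) set against the ground-truth set, and derives
#' precision, recall and the F1-score (harmonic mean). Degenerate
#' denominators yield 0 by convention.
#'
#' Inputs may be logical vectors over a common universe, integer index
#' sets, or (for graphs) symmetric adjacency matrices, which are compared
#' over the upper triangle in [edge_pairs()] order.
#'
#' @param selected selected set.
#' @param truth true set.
#' @return an object of class \code{"selection_performance"}: list with
#'   \code{tp}, \code{fp}, \code{fn}, \code{precision}, \code{recall},
#'   \code{f1}.
#' @export
#' @examples
#' selection_performance(c(1, 2, 3, 4), truth = c(2, 3, 9))
selection_performance <- function(selected, truth) {
  as_logical_set <- function(s) {
    if (is.matrix(s)) {
      if (!.is_symmetric(s)) stop("adjacency input must be symmetric")
      .edge_support(s)
    } else if (is.logical(s)) {
      s
    } else {
      s
    }
  }
  selected <- as_logical_set(selected)
  truth <- as_logical_set(truth)
  if (is.logical(selected) && is.logical(truth)) {
    if (length(selected) != length(truth)) {
      stop("logical inputs must share the same universe length")
    }
    tp <- sum(selected & truth)
    fp <- sum(selected & !truth)
    fn <- sum(!selected & truth)
  } else {
    selected <- if (is.logical(selected)) which(selected) else selected
    truth <- if (is.logical(truth)) which(truth) else truth
    tp <- length(intersect(selected, truth))
    fp <- length(setdiff(selected, truth))
    fn <- length(setdiff(truth, selected))
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1),
            class = "selection_performance")
}

#' @export
print.selection_performance <- function(x, ...) {
  cat(sprintf(
    "TP %d, FP %d, FN %d | precision %.3f, recall %.3f, F1 %.3f\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

# rank-statistic AUC (equivalent to the Wilcoxon statistic)
.auc <- function(score, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Incremental unpenalised refit curve
#'
#' Post-hoc assessment of a calibrated selection: predictors are added one
#' at a time in decreasing order of selection proportion (ties broken by
#' ascending feature index) to an unpenalised model refitted on a random
#' half of the data, and out-of-sample performance (R-squared for the
#' gaussian family, AUC for the binomial family) is evaluated on the other
#' half. A plateau after the calibrated model size indicates that the
#' stable set captures most of the explanatory information.
#'
#' @param x predictor matrix.
#' @param y outcome.
#' @param proportions selection proportions of all p features (e.g.
#'   \code{coef} of a [stabsel()] fit).
#' @param n_splits number of random train/test splits (default 100).
#' @param train_fraction fraction of observations used for refitting.
#' @param family \code{"gaussian"} or \code{"binomial"}.
#' @param k_max largest model size; defaults to the largest size the
#'   training half can support.
#' @param seed optional integer seed for the splits.
#' @return data frame with columns \code{k}, \code{feature} (the feature
#'   entering at size k), \code{median}, \code{q5}, \code{q95}.
#' @export
incremental_refit_curve <- function(x, y, proportions, n_splits = 100,
                                    train_fraction = 0.5,
                                    family = c("gaussian", "binomial"),
                                    k_max = NULL, seed = NULL) {
  family <- match.arg(family)
  x <- .check_matrix(x, "x")
  if (length(proportions) != ncol(x)) {
    stop("'proportions' must have one value per feature")
  }
  n <- nrow(x)
  n_train <- floor(train_fraction * n)
  ord <- order(-proportions, seq_along(proportions))
  if (is.null(k_max)) k_max <- min(ncol(x), n_train - 2L)
  if (k_max > n_train - 2L) {
    stop("k_max exceeds what the training half can support (", n_train - 2L,
         ")")
  }
  if (!is.null(seed)) set.seed(seed)

  perf <- matrix(NA_real_, n_splits, k_max)
  for (s in seq_len(n_splits)) {
    tr <- sample.int(n, n_train)
    te <- setdiff(seq_len(n), tr)
    for (k in seq_len(k_max)) {
      cols <- ord[seq_len(k)]
      xtr <- cbind(1, x[tr, cols, drop = FALSE])
      xte <- cbind(1, x[te, cols, drop = FALSE])
      if (family == "gaussian") {
        fit <- stats::lm.fit(xtr, y[tr])
        pred <- as.vector(xte %*% ifelse(is.na(fit$coefficients), 0,
                                         fit$coefficients))
        sse <- sum((y[te] - pred)^2)
        sst <- sum((y[te] - mean(y[te]))^2)
        perf[s, k] <- 1 - sse / sst
      } else {
        df <- as.data.frame(x[tr, cols, drop = FALSE])
        names(df) <- paste0("f", seq_len(k))
        df$y <- y[tr]
        fit <- suppressWarnings(
          stats::glm(y ~ ., data = df, family = stats::binomial()))
        nd <- as.data.frame(x[te, cols, drop = FALSE])
        names(nd) <- paste0("f", seq_len(k))
        pred <- suppressWarnings(
          stats::predict(fit, newdata = nd, type = "link"))
        perf[s, k] <- .auc(pred, y[te])
      }
    }
  }
  data.frame(
    k = seq_len(k_max),
    feature = ord[seq_len(k_max)],
    median = apply(perf, 2, stats::median, na.rm = TRUE),
    q5 = apply(perf, 2, stats::quantile, probs = 0.05, na.rm = TRUE),
    q95 = apply(perf, 2, stats::quantile, probs = 0.95, na.rm = TRUE)
  )
}
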