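#' Enumerate the edges of an undirected graph on p nodes
#'
#' Edges (unordered node pairs, no self-loops) are listed in upper-triangular
#' row-major order: (1,2), (1,3), ..., (1,p), (2,3), ..., (p-1,p). All
#' selection-count matrices, stability surfaces and performance metrics for
#' graphical models share this ordering, so a flat edge index always refers
#' to the same node pair.
#'
#' @param p number of nodes.
#' @return integer matrix with \code{p*(p-1)/2} rows and columns \code{i}, \code{j}
#'   with \code{i < j}.
#' @export
#' @examples
#' edge_pairs(4)
edge_pairs <- function(p) {
  p <- .check_count(p, min = 2L, what = "p")
  i <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  j <- sequence((p - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Flat edge index of a node pair
#'
#' Inverse of [edge_pairs()]: maps an unordered pair to its position in the
#' row-major upper-triangular enumeration.
#'
#' @param i,j node indices (vectors allowed; order of the pair is irrelevant).
#' @param p number of nodes.
#' @return integer vector of indices in \code{1..p*(p-1)/2}.
#' @export
edge_index <- function(i, j, p) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  if (any(lo < 1L) || any(hi > p) || any(lo == hi)) {
    stop("edge indices must satisfy 1 <= i != j <= p")
  }
  as.integer((lo - 1L) * (2L * p - lo) / 2L + (hi - lo))
}

# linear positions of the (i, j) and (j, i) entries of a p x p matrix,
# in edge_pairs() order; used to read edge supports off precision matrices
.edge_linear_idx <- function(p) {
  ep <- edge_pairs(p)
  list(
    upper = (ep[, 2L] - 1L) * p + ep[, 1L],
    lower = (ep[, 1L] - 1L) * p + ep[, 2L]
  )
}

# symmetric off-diagonal support of a (possibly slightly asymmetric) matrix,
# as a logical vector over edge_pairs(p); an edge is present if either of the
# two mirrored entries exceeds the threshold
.edge_support <- function(m, tol = 1e-8) {
  idx <- .edge_linear_idx(nrow(m))
  abs(m[idx$upper]) > tol | abs(m[idx$lower]) > tol
}

# input validation helpers shared across modules
.check_count <- function(x, min, what) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %d", what, min))
  }
  as.integer(x)
}

.check_prob <- function(x, what, open_lower = FALSE, open_upper = FALSE) {
  lo_ok <- if (open_lower) x > 0 else x >= 0
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || !lo_ok || !hi_ok) {
    stop(sprintf("'%s' must be a single value in %s0, 1%s", what,
                 if (open_lower) "(" else "[", if (open_upper) ")" else "]"))
  }
  as.numeric(x)
}

.check_matrix <- function(x, what = "x") {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop(sprintf("'%s' must be a numeric matrix", what))
  if (anyNA(x)) stop(sprintf("'%s' contains missing values", what))
  x
}

.is_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}
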