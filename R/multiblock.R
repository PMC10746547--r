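#' Block structure induced by feature groups
#'
#' G a-priori feature groups (e.g. OMICs platforms) partition the
#' \eqn{N = p(p-1)/2} candidate edges into \eqn{B = G(G+1)/2} blocks: one
#' within-group block per group and one cross block per unordered group
#' pair. Blocks are ordered row-major over group pairs: (1,1), (1,2), ...,
#' (1,G), (2,2), ...
#'
#' @param groups vector of length p of group labels (integer, character or
#'   factor); groups are numbered by sorted unique label.
#' @return an object of class \code{"block_structure"}: list with the
#'   number of groups \code{G}, number of blocks \code{B}, the integer
#'   \code{block_of_edge} vector over [edge_pairs()] order,
#'   \code{block_sizes}, the \code{block_pairs} (group pair per block) and
#'   logical \code{within} flags.
#' @export
#' @examples
#' block_index_sets(c(1, 1, 2, 2))
block_index_sets <- function(groups) {
  if (length(groups) < 2L || anyNA(groups)) {
    stop("'groups' must be a complete label vector of length p >= 2")
  }
  labels <- sort(unique(groups))
  g <- match(groups, labels)
  G <- length(labels)
  sizes <- tabulate(g, G)
  if (any(sizes < 2L)) {
    stop("every group must contain at least 2 features (within-block edges)")
  }
  p <- length(g)
  # block id for group pair (a <= b), row-major over the G x G upper triangle
  pair_block <- matrix(0L, G, G)
  b <- 0L
  for (a in seq_len(G)) {
    for (bb in a:G) {
      b <- b + 1L
      pair_block[a, bb] <- pair_block[bb, a] <- b
    }
  }
  ep <- edge_pairs(p)
  block_of_edge <- pair_block[cbind(g[ep[, 1]], g[ep[, 2]])]
  B <- G * (G + 1L) / 2L
  block_pairs <- which(upper.tri(pair_block, diag = TRUE), arr.ind = TRUE)
  block_pairs <- block_pairs[order(pair_block[block_pairs]), , drop = FALSE]
  colnames(block_pairs) <- c("group1", "group2")

  structure(list(groups = g, labels = labels, G = G, B = B, p = p,
                 N = nrow(ep), block_of_edge = block_of_edge,
                 block_sizes = tabulate(block_of_edge, B),
                 block_pairs = block_pairs,
                 within = block_pairs[, 1] == block_pairs[, 2],
                 group_within_block = diag(pair_block)),
            class = "block_structure")
}

#' @export
print.block_structure <- function(x, ...) {
  cat(sprintf("Block structure: %d groups, %d blocks over %d edges\n",
              x$G, x$B, x$N))
  for (b in seq_len(x$B)) {
    cat(sprintf("  block %d (%s groups %d-%d): %d edges\n", b,
                if (x$within[b]) "within" else "between",
                x$block_pairs[b, 1], x$block_pairs[b, 2], x$block_sizes[b]))
  }
  invisible(x)
}

#' Block penalty matrix for the graphical LASSO
#'
#' Builds the p x p penalty matrix used to calibrate one block: edges of the
#' target block are penalised with \code{lambda_b}, edges of all other
#' blocks with the weak penalty \code{lambda0} (so that partial correlations
#' in the target block remain conditional on all nodes). The diagonal is
#' unpenalised, matching the scalar solver's convention.
#'
#' @param blocks a [block_index_sets()] object.
#' @param b target block index in 1..B.
#' @param lambda_b penalty on the target block (>= 0).
#' @param lambda0 weak penalty on every other block (>= 0; default 0.1).
#' @return symmetric p x p penalty matrix with zero diagonal.
#' @export
block_penalty_matrix <- function(blocks, b, lambda_b, lambda0 = 0.1) {
  stopifnot(inherits(blocks, "block_structure"))
  if (lambda_b < 0 || lambda0 < 0) stop("penalties must be nonnegative")
  b <- .check_count(b, min = 1L, what = "b")
  if (b > blocks$B) stop("'b' exceeds the number of blocks")
  lam_edge <- ifelse(blocks$block_of_edge == b, lambda_b, lambda0)
  .penalty_from_edges(lam_edge, blocks$p)
}

# assemble a symmetric penalty matrix from per-edge penalties
.penalty_from_edges <- function(lam_edge, p, diagonal = 0) {
  P <- matrix(0, p, p)
  ep <- edge_pairs(p)
  P[ep] <- lam_edge
  P <- P + t(P)
  diag(P) <- diagonal
  P
}

# correlation matrices of each resampling unit (pairs of matrices for cpss)
.resample_correlations <- function(x, resamples, scheme) {
  lapply(resamples, function(r) {
    if (scheme == "cpss") {
      list(stats::cor(x[r$a, , drop = FALSE]),
           stats::cor(x[r$b, , drop = FALSE]))
    } else {
      list(stats::cor(x[r, , drop = FALSE]))
    }
  })
}

# per-block penalty grid: from the empty-block penalty down to the largest
# penalty reaching `target_density` of the block's edges on the full data,
# with every other block held at lambda0
.block_lambda_grid <- function(S, blocks, b, lambda0, size,
                               target_density = 0.5, tol = 1e-4,
                               max_iter = 100) {
  in_block <- blocks$block_of_edge == b
  ep <- edge_pairs(blocks$p)[in_block, , drop = FALSE]
  lambda_max <- max(abs(S[ep]))
  nb <- sum(in_block)
  density_at_raw <- function(lam, warm) {
    fit <- glasso_solve(S, block_penalty_matrix(blocks, b, lam, lambda0),
                        tol = tol, max_iter = max_iter, warm = warm)
    list(density = sum(fit$selection[in_block]) / nb, fit = fit)
  }
  density_at <- function(lam, warm) {
    tryCatch(density_at_raw(lam, warm), error = function(e) NULL)
  }
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
    for (step in 1:8) {
      mid <- sqrt(lo * hi)
      d <- density_at(mid, warm)
      if (is.null(d)) break
      warm <- d$fit
      if (d$density >= target_density) lo <- mid else hi <- mid
    }
  }
  exp(seq(log(lambda_max), log(lo), length.out = size))
}

# selection counts for the edges of one block under a penalty path on that
# block (others at lambda0), given precomputed resample correlations
.block_counts <- function(cors, blocks, b, values, lambda0, tol, max_iter) {
  in_block <- blocks$block_of_edge == b
  H <- matrix(0L, sum(in_block), length(values))
  for (k in seq_along(cors)) {
    sel_unit <- NULL
    for (half in cors[[k]]) {
      warm <- NULL
      sel <- matrix(FALSE, sum(in_block), length(values))
      for (l in seq_along(values)) {
        fit <- glasso_solve(half,
                            block_penalty_matrix(blocks, b, values[l],
                                                 lambda0),
                            tol = tol, max_iter = max_iter, warm = warm)
        warm <- fit
        sel[, l] <- fit$selection[in_block]
      }
      sel_unit <- if (is.null(sel_unit)) sel else (sel_unit & sel)
    }
    H <- H + sel_unit
  }
  H
}

#' Multi-block stability selection graphical model
#'
#' Calibrates a stability selection graphical LASSO separately within each
#' block of edges induced by a-priori feature groups. For each block, the
#' graphical LASSO is fitted on resampled data with a block penalty matrix
#' (target block at \eqn{\lambda_b}, all other blocks at the weak penalty
#' \eqn{\lambda_0}), and \eqn{(\lambda_b, \pi_b)} is calibrated by
#' maximising a block-specific stability score computed from the counts of
#' the block's edges only. The final model is the union of the
#' block-specific stable edge sets. Under a PFER constraint, the overall
#' budget \code{eta} is split across blocks proportionally to block size
#' and the per-block bounds (computed on the block's edge universe) are
#' constrained at their share, so the summed bound stays below \code{eta}.
#'
#' @inheritParams stabsel
#' @param groups feature group labels of length p.
#' @param lambda0 weak penalty on off-target blocks (default 0.1).
#' @return an object of class \code{"stabsel_multiblock"}: list with the
#'   [block_index_sets()] structure, one calibration per block (penalty
#'   grid, surface, \code{lambda_hat}, \code{pi_hat}, proportions, stable
#'   flags), the union \code{adjacency}, and the summed PFER bound.
#' @export
stabsel_multiblock <- function(x, groups, K = 100,
                               scheme = c("subsample", "bootstrap", "cpss"),
                               fraction = 0.5, lambda0 = 0.1,
                               n_lambda = 50, pi_grid = pi_grid_default(),
                               pfer = c("none", "mb", "ss"), eta = Inf,
                               tol = 1e-3, max_iter = 100, seed = NULL) {
  scheme <- match.arg(scheme)
  pfer <- match.arg(pfer)
  x <- .check_matrix(x, "x")
  blocks <- block_index_sets(groups)
  if (blocks$p != ncol(x)) stop("'groups' must have one label per column")
  S <- stats::cor(x)
  resamples <- draw_resamples(nrow(x), K = K, scheme = scheme,
                              fraction = fraction, seed = seed)
  cors <- .resample_correlations(x, resamples, scheme)

  per_block <- vector("list", blocks$B)
  total_bound <- 0
  for (b in seq_len(blocks$B)) {
    values <- .block_lambda_grid(S, blocks, b, lambda0, n_lambda,
                                 tol = tol, max_iter = max_iter)
    H <- .block_counts(cors, blocks, b, values, lambda0, tol, max_iter)
    colnames(H) <- signif(values, 6)
    surface <- score_surface(H, pi_grid = pi_grid, K = K)
    surface$lambda <- values
    eta_b <- if (pfer == "none") Inf else
      eta * blocks$block_sizes[b] / blocks$N
    cal <- tryCatch(
      calibrate_surface(surface, pfer = pfer, eta = eta_b),
      error = function(e) stop(sprintf("block %d: %s", b,
                                       conditionMessage(e)), call. = FALSE))
    proportions <- H[, cal$lambda_index] / K
    stable <- proportions >= cal$pi_hat - .EPS
    per_block[[b]] <- list(block = b, lambda = values, surface = surface,
                           calibration = cal,
                           lambda_hat = cal$lambda_hat,
                           pi_hat = cal$pi_hat,
                           score_max = cal$score_max,
                           eta_b = eta_b,
                           proportions = proportions, stable = stable)
    if (!is.null(cal$bound)) total_bound <- total_bound + cal$bound
  }

  ep <- edge_pairs(blocks$p)
  adjacency <- matrix(0L, blocks$p, blocks$p,
                      dimnames = list(colnames(x), colnames(x)))
  stable_all <- logical(blocks$N)
  proportions_all <- numeric(blocks$N)
  for (b in seq_len(blocks$B)) {
    in_block <- blocks$block_of_edge == b
    stable_all[in_block] <- per_block[[b]]$stable
    proportions_all[in_block] <- per_block[[b]]$proportions
  }
  adjacency[ep[stable_all, , drop = FALSE]] <- 1L
  adjacency <- adjacency + t(adjacency)

  structure(list(call = match.call(), blocks = blocks, lambda0 = lambda0,
                 K = K, scheme = scheme, per_block = per_block,
                 adjacency = adjacency, stable = stable_all,
                 proportions = proportions_all,
                 pfer = pfer, eta = if (pfer == "none") NULL else eta,
                 total_bound = if (pfer == "none") NULL else total_bound,
                 seed = seed),
            class = "stabsel_multiblock")
}

#' @export
print.stabsel_multiblock <- function(x, ...) {
  cat(sprintf(
    "Multi-block stability selection graphical LASSO (%d blocks, lambda0 = %g)\n",
    x$blocks$B, x$lambda0))
  for (pb in x$per_block) {
    cat(sprintf(
      "  block %d: lambda = %.4g, pi = %.2f, %d/%d edges stable (score %.2f)\n",
      pb$block, pb$lambda_hat, pb$pi_hat, sum(pb$stable),
      length(pb$stable), pb$score_max))
  }
  if (!is.null(x$total_bound)) {
    cat(sprintf("  total PFER bound %.2f <= eta = %g\n", x$total_bound,
                x$eta))
  }
  cat(sprintf("  union graph: %d edges\n", sum(x$stable)))
  invisible(x)
}

# category score from counts with an externally supplied gamma; used both
# by stability_score (gamma = q/N from the same counts) and by the joint
# multi-block calibration (gamma shared across blocks). A category that is
# observed but has null probability zero (gamma degenerate at 0 or 1) makes
# the score uninformative: 0 by convention.
.score_with_gamma <- function(h, K, pi, gamma, two_categories = FALSE) {
  lp <- .category_logprobs(K, gamma, pi)
  ct <- .category_counts(h, K, pi)
  if (two_categories) {
    c_hi <- ceiling(K * pi - .EPS) - 1
    lp <- c(sel = lp[["sel"]],
            other = stats::pbinom(c_hi, K, gamma, log.p = TRUE))
    ct <- c(sel = ct[["sel"]], other = length(h) - ct[["sel"]])
  }
  used <- ct > 0
  if (any(!is.finite(lp[used]))) return(0)
  max(-sum(ct[used] * lp[used]), 0)
}

#' Joint multi-block calibration over a product penalty grid
#'
#' Calibrates all block penalties simultaneously: graphical LASSO models
#' are fitted with a penalty matrix assigning \eqn{\lambda_b} to every block
#' at once (no weak penalty), over the product grid of per-block penalty
#' values, and the joint stability score (sum of block scores sharing one
#' null selection probability \eqn{\gamma}) is maximised over the penalty
#' vector and the per-block thresholds. The product grid grows as
#' \code{n_lambda^B}, so this is only practical for coarse grids and few
#' blocks; it exists chiefly for comparison with the block-wise
#' decomposition of [stabsel_multiblock()], which tends to select better.
#' Penalty vectors whose fits break down numerically (all blocks weakly
#' penalised on a rank-deficient resample covariance) are dropped from the
#' search.
#'
#' @inheritParams stabsel_multiblock
#' @param n_lambda per-block grid size (coarse; default 5).
#' @param max_blocks refuse more blocks than this (default 3).
#' @param max_cells refuse product grids larger than this (default 500).
#' @return an object of class \code{"stabsel_jointblocks"}: list with the
#'   best penalty vector \code{lambda_hat}, per-block \code{pi_hat}, the
#'   union \code{adjacency}, stable flags and proportions.
#' @export
stabsel_joint_blocks <- function(x, groups, K = 100,
                                 scheme = c("subsample", "bootstrap", "cpss"),
                                 fraction = 0.5, n_lambda = 5,
                                 pi_grid = pi_grid_default(),
                                 lambda0 = 0.1, max_blocks = 3,
                                 max_cells = 500,
                                 tol = 1e-3, max_iter = 100, seed = NULL) {
  scheme <- match.arg(scheme)
  x <- .check_matrix(x, "x")
  blocks <- block_index_sets(groups)
  if (blocks$B > max_blocks) {
    stop("joint calibration is capped at ", max_blocks, " blocks")
  }
  if (n_lambda^blocks$B > max_cells) {
    stop("product grid has more than ", max_cells,
         " cells; reduce 'n_lambda'")
  }
  S <- stats::cor(x)
  # per-block ranges reuse the block-wise grid construction (the weak
  # penalty only enters the range search, not the joint fits)
  grids <- lapply(seq_len(blocks$B), function(b) {
    .block_lambda_grid(S, blocks, b, lambda0, n_lambda,
                       tol = tol, max_iter = max_iter)
  })
  cells <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  colnames(cells) <- paste0("lambda", seq_len(blocks$B))
  n_cells <- nrow(cells)

  resamples <- draw_resamples(nrow(x), K = K, scheme = scheme,
                              fraction = fraction, seed = seed)
  cors <- .resample_correlations(x, resamples, scheme)

  H <- matrix(0L, blocks$N, n_cells)
  valid <- rep(TRUE, n_cells)
  for (k in seq_len(K)) {
    sel_unit <- NULL
    for (half in cors[[k]]) {
      warm <- NULL
      sel <- matrix(FALSE, blocks$N, n_cells)
      for (cc in seq_len(n_cells)) {
        if (!valid[cc]) next
        lam_edge <- cells[cc, blocks$block_of_edge]
        fit <- tryCatch(
          glasso_solve(half, .penalty_from_edges(lam_edge, blocks$p),
                       tol = tol, max_iter = max_iter, warm = warm),
          error = function(e) NULL)
        if (is.null(fit)) {
          valid[cc] <- FALSE
          warm <- NULL
          next
        }
        warm <- fit
        sel[, cc] <- fit$selection
      }
      sel_unit <- if (is.null(sel_unit)) sel else (sel_unit & sel)
    }
    H <- H + sel_unit
  }
  if (!any(valid)) {
    stop("no penalty vector in the product grid could be estimated")
  }

  best <- list(score = -Inf)
  for (cc in which(valid)) {
    q <- model_size_q(H[, cc], K)
    gamma <- q / blocks$N
    pi_hat <- numeric(blocks$B)
    total <- 0
    for (b in seq_len(blocks$B)) {
      hb <- H[blocks$block_of_edge == b, cc]
      sb <- vapply(pi_grid, function(pp)
        .score_with_gamma(hb, K, pp, gamma), numeric(1))
      m <- max(sb)
      # ties toward the largest threshold
      pi_hat[b] <- pi_grid[max(which(sb == m))]
      total <- total + m
    }
    if (total > best$score) {
      best <- list(score = total, cell = cc, pi_hat = pi_hat,
                   q = q, gamma = gamma)
    }
  }

  proportions <- H[, best$cell] / K
  stable <- proportions >= (best$pi_hat[blocks$block_of_edge] - .EPS)
  ep <- edge_pairs(blocks$p)
  adjacency <- matrix(0L, blocks$p, blocks$p,
                      dimnames = list(colnames(x), colnames(x)))
  adjacency[ep[stable, , drop = FALSE]] <- 1L
  adjacency <- adjacency + t(adjacency)

  structure(list(call = match.call(), blocks = blocks,
                 lambda_hat = cells[best$cell, ], pi_hat = best$pi_hat,
                 score_max = best$score, K = K,
                 adjacency = adjacency, stable = stable,
                 proportions = proportions, grids = grids, seed = seed),
            class = "stabsel_jointblocks")
}

#' @export
print.stabsel_jointblocks <- function(x, ...) {
  cat(sprintf(
    "Joint multi-block stability selection (%d blocks, score %.2f)\n",
    x$blocks$B, x$score_max))
  cat("  lambda:", paste(signif(x$lambda_hat, 4), collapse = ", "), "\n")
  cat("  pi:    ", paste(signif(x$pi_hat, 3), collapse = ", "), "\n")
  cat(sprintf("  union graph: %d edges\n", sum(x$stable)))
  invisible(x)
}

#' Export a multi-block fit as an edge-list CSV
#'
#' Columns: node1, node2, block, selection_proportion, stable_flag.
#'
#' @param object a [stabsel_multiblock()] fit.
#' @param path output file.
#' @export
write_multiblock_edges <- function(object, path) {
  stopifnot(inherits(object, "stabsel_multiblock"))
  ep <- edge_pairs(object$blocks$p)
  df <- data.frame(node1 = ep[, 1], node2 = ep[, 2],
                   block = object$blocks$block_of_edge,
                   selection_proportion = object$proportions,
                   stable_flag = as.integer(object$stable))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
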