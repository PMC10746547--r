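#' Write a simulated dataset to plain-text files
#'
#' Writes the data matrix as CSV (samples x features with a header row of
#' feature names), the true adjacency as a two-column edge-list CSV and the
#' precision matrix as CSV. Used by the command-line interface; the files
#' round-trip with [utils::read.csv()].
#'
#' @param sim a [simulate_graph_data()] or [simulate_regression_data()]
#'   object.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  xp <- file.path(dir, paste0(prefix, "_X.csv"))
  utils::write.csv(as.data.frame(sim$X), xp, row.names = FALSE)
  paths <- c(paths, xp)
  if (inherits(sim, "graph_simulation")) {
    ep <- edge_pairs(sim$p)
    on <- .edge_support(sim$theta)
    elp <- file.path(dir, paste0(prefix, "_edges.csv"))
    utils::write.csv(data.frame(node1 = ep[on, 1], node2 = ep[on, 2]),
                     elp, row.names = FALSE)
    op <- file.path(dir, paste0(prefix, "_omega.csv"))
    utils::write.csv(as.data.frame(sim$omega), op, row.names = FALSE)
    paths <- c(paths, elp, op)
  } else {
    yp <- file.path(dir, paste0(prefix, "_y.csv"))
    utils::write.csv(data.frame(y = sim$y), yp, row.names = FALSE)
    bp <- file.path(dir, paste0(prefix, "_beta.csv"))
    utils::write.csv(data.frame(feature = colnames(sim$X), beta = sim$beta),
                     bp, row.names = FALSE)
    paths <- c(paths, yp, bp)
  }
  invisible(paths)
}
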