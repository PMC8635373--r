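#' Binary graph from adjacency
#'
#' Light wrapper marking a 0/1 symmetric zero-diagonal adjacency matrix.
#' Shortest-path lengths are hop counts, computed on demand by
#' [graph_distances()].
#'
#' @param adjacency Square 0/1 matrix (logical or numeric).
#' @return A `binary_graph` (numeric 0/1 matrix).
#' @export
binary_graph <- function(adjacency) {
  a <- (unclass(adjacency) != 0) * 1
  if (!is.matrix(a) || nrow(a) != ncol(a)) stop("adjacency must be square")
  if (max(abs(a - t(a))) > 0) stop("adjacency must be symmetric")
  diag(a) <- 0
  structure(a, class = c("binary_graph", "matrix", "array"))
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges\n",
              nrow(x), sum(x[upper.tri(x)])))
  invisible(x)
}

#' Threshold a structural connectivity matrix
#'
#' Builds the binary structural network: regions are connected iff one or
#' more fibers (probabilistic streamlines) link them, i.e. the adjacency
#' is `sc >= 1`. Idempotent under rescaling of positive counts.
#'
#' @param sc SC `connectivity_matrix` (non-negative fiber counts).
#' @return A [binary_graph()].
#' @export
threshold_structural <- function(sc) {
  if (any(sc < 0)) stop("SC matrix has negative entries")
  binary_graph(unclass(sc) >= 1)
}

#' Threshold a functional connectivity matrix at FDR-significant positive edges
#'
#' The functional network keeps the edges whose Fisher-z correlation is
#' positive and significantly nonzero at false discovery rate `q`. Each
#' upper-triangle edge gets a two-sided p-value from the Fisher-z normal
#' approximation, `p = 2 * (1 - pnorm(|z| * sqrt(t_points - 3)))`, where
#' `t_points` is the length of the time series the correlations were
#' estimated from (the z statistic has standard error `1/sqrt(t - 3)`).
#' Benjamini-Hochberg correction is applied across all upper-triangle
#' edges of the matrix being thresholded; surviving positive edges are
#' binarized.
#'
#' @param fc FC `connectivity_matrix` (Fisher-z values).
#' @param t_points Time-series length; must exceed 3 for the z standard
#'   error to be defined.
#' @param q FDR level (default 0.05).
#' @return A [binary_graph()].
#' @export
threshold_functional <- function(fc, t_points, q = 0.05) {
  if (t_points <= 3) stop("t_points must exceed 3 (Fisher-z SE undefined)")
  stopifnot(q > 0, q < 1)
  z <- unclass(fc)
  ut <- upper.tri(z)
  p <- 2 * stats::pnorm(-abs(z[ut]) * sqrt(t_points - 3))
  keep <- stats::p.adjust(p, method = "BH") <= q & z[ut] > 0
  adj <- matrix(0, nrow(z), ncol(z), dimnames = dimnames(z))
  adj[ut] <- keep * 1
  binary_graph(adj + t(adj))
}

# All-pairs hop distances by simultaneous breadth-first search: the k-th
# frontier of every source is expanded at once with one boolean matrix
# product per level. Unreached pairs stay Inf.
graph_distances <- function(g) {
  a <- unclass(g)
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  frontier <- a
  k <- 1
  while (any(frontier > 0)) {
    newly <- frontier > 0 & is.infinite(d)
    d[newly] <- k
    reached <- is.finite(d)
    frontier <- (frontier %*% a > 0) * !reached
    k <- k + 1
  }
  dimnames(d) <- dimnames(a)
  d
}

#' Global efficiency of a binary graph
#'
#' Mean inverse shortest-path length over all ordered node pairs:
#' `Eglob = 1/(N(N-1)) * sum_{i != j} 1/d(i,j)`, with `d(i,j)` the hop
#' count of the shortest path and `1/d = 0` for disconnected pairs.
#' Equals 1 exactly when the graph is complete and decreases as the
#' network becomes sparse or fragmented; it is monotone non-decreasing
#' under edge addition.
#'
#' @param g A [binary_graph()] (or 0/1 adjacency matrix) with at least 2
#'   nodes.
#' @return Efficiency in `[0, 1]`.
#' @examples
#' k4 <- binary_graph(1 - diag(4))
#' global_efficiency(k4)  # 1
#' @export
global_efficiency <- function(g) {
  if (!inherits(g, "binary_graph")) g <- binary_graph(g)
  n <- nrow(g)
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  d <- graph_distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}
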