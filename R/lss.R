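# Weighted least squares on difference (adjacency) systems: the shared
# solver behind tile positioning, sub-tile histogram shifts and the
# rough/fine per-grid-point delta reconciliation.

#' Construct a delta graph
#'
#' A delta graph holds directed difference measurements between nodes:
#' each edge states that `coord[dst] - coord[src]` was measured as
#' `delta`. Deltas may be 1D (scalar shifts) or 2D (x,y in nm); both axes
#' share the adjacency and are solved independently.
#'
#' @param n_nodes number of nodes.
#' @param src,dst integer node indices (1-based).
#' @param delta numeric matrix (n_edges x n_axes) or vector of measured
#'   differences.
#' @param weight non-negative edge weights (default 1).
#' @param outlier,replaced logical flags per edge.
#' @return object of class `delta_graph`.
#' @export
delta_graph <- function(n_nodes, src, dst, delta, weight = NULL,
                        outlier = NULL, replaced = NULL) {
  delta <- as.matrix(delta)
  m <- length(src)
  stopifnot(length(dst) == m, nrow(delta) == m)
  if (is.null(weight)) weight <- rep(1, m)
  if (is.null(outlier)) outlier <- rep(FALSE, m)
  if (is.null(replaced)) replaced <- rep(FALSE, m)
  if (any(src == dst)) stop("self-edges are not allowed")
  if (any(weight < 0)) stop("edge weights must be >= 0")
  if (m && (max(src, dst) > n_nodes || min(src, dst) < 1))
    stop("node index out of range")
  structure(list(n_nodes = as.integer(n_nodes),
                 src = as.integer(src), dst = as.integer(dst),
                 delta = delta, weight = as.numeric(weight),
                 outlier = outlier, replaced = replaced),
            class = "delta_graph")
}

# connected components of the undirected adjacency; error if > 1
check_connected <- function(graph) {
  g <- igraph::graph_from_edgelist(cbind(graph$src, graph$dst), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, graph$n_nodes - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    smallest <- which(comp$membership == which.min(comp$csize))
    stop("delta graph is disconnected (", comp$no, " components; smallest: nodes ",
         paste(utils::head(smallest, 10), collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' Build the sparse difference system for a delta graph
#'
#' One row per edge with +1 at the destination and -1 at the source node, so
#' that `A %*% coords = delta` encodes `coord[dst] - coord[src] = delta`.
#'
#' @param graph a [delta_graph()].
#' @param check_connectivity error on disconnected graphs (default TRUE).
#' @return list with sparse `A` (n_edges x n_nodes), `b` (deltas), `w`
#'   (weights).
#' @export
build_system <- function(graph, check_connectivity = TRUE) {
  if (check_connectivity) check_connected(graph)
  m <- length(graph$src)
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(m), 2L),
    j = c(graph$dst, graph$src),
    x = rep(c(1, -1), each = m),
    dims = c(m, graph$n_nodes))
  list(A = A, b = graph$delta, w = graph$weight)
}

#' Solve a difference system by (optionally ridge-regularized) least squares
#'
#' Minimizes `sum_e w_e || (x[dst_e] - x[src_e]) - delta_e ||^2 + l2 ||x||^2`
#' per axis. With `l2 = 0` the gauge freedom (a global offset per axis) is
#' fixed by constraining the solution mean to zero, which coincides with the
#' minimum-norm least-squares solution; the offset is then reported as
#' removed bias. Callers needing per-z linear trend removal apply
#' [remove_linear_trend()] on top.
#'
#' @param system output of [build_system()], or a [delta_graph()].
#' @param l2 non-negative ridge factor.
#' @return list of class `solved_coords`: `coords` (n_nodes x n_axes),
#'   `residuals` (n_edges x n_axes, measured minus fitted delta),
#'   `bias_removed` (subtracted per-axis offsets).
#' @export
solve_deltas <- function(system, l2 = 0) {
  if (inherits(system, "delta_graph")) system <- build_system(system)
  stopifnot(l2 >= 0)
  A <- system$A; b <- as.matrix(system$b); w <- system$w
  if (any(!is.finite(w)) || any(!is.finite(b))) stop("non-finite weights or deltas")
  n <- ncol(A)
  AtW <- Matrix::t(A * w)           # row-scaled by weights
  M <- AtW %*% A
  if (l2 > 0) {
    M <- M + Matrix::Diagonal(n, l2)
  } else {
    # gauge fix: append the constraint sum(x) = 0 (exactly satisfiable by
    # the minimum-norm LS solution, so it does not perturb the fit)
    M <- M + Matrix::Matrix(1, n, n) / n
  }
  rhs <- AtW %*% b
  x <- tryCatch(as.matrix(Matrix::solve(M, rhs)),
                error = function(e) stop("difference system is rank deficient beyond gauge freedom: ",
                                         conditionMessage(e)))
  offs <- colMeans(x)
  x <- sweep(x, 2, offs)
  fitted <- as.matrix(A %*% x)
  structure(list(coords = x, residuals = b - fitted, bias_removed = offs),
            class = "solved_coords")
}

#' Remove the least-squares linear trend from a per-z sequence
#'
#' Fits `value ~ slope * z + offset` by ordinary least squares and subtracts
#' the fit; used per grid point and per axis when reconciling blockwise
#' z-chains, where the solver is susceptible to offset and linear-trend
#' biases.
#'
#' @param values numeric vector (or matrix with one column per axis).
#' @param z integer/numeric coordinates, same length as `nrow(values)`.
#' @return list: `values` detrended, `slope`, `offset` (per axis).
#' @export
remove_linear_trend <- function(values, z) {
  values <- as.matrix(values)
  if (length(unique(z)) < 2) stop("need >= 2 distinct z coordinates to fit a trend")
  X <- cbind(1, z)
  coef <- qr.coef(qr(X), values)
  list(values = values - X %*% coef,
       slope = coef[2, ], offset = coef[1, ])
}
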