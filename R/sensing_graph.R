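# m-nearest-neighbour sensing graphs and their Laplacians.
#
# Edge direction convention: i -> j means "i senses j" (information about j
# reaches i). Consensus is feasible iff some node is reachable from every
# node along sensing edges, i.e. the strongly-connected-component
# condensation has exactly one sink.

# Internal k-NN search: brute-force all-pairs distances with deterministic
# tie-breaking (ascending index). Returns closest-first index and distance
# matrices (N x m).
knn_internal <- function(x, m) {
  n <- nrow(x)
  if (m < 1L) stop("m must be at least 1")
  if (m > n - 1L) stop("m exceeds N-1")
  if (anyDuplicated(x)) stop("coincident positions in point cloud")
  d <- as.matrix(stats::dist(x))
  idx <- matrix(0L, n, m)
  dm <- matrix(0, n, m)
  ids <- seq_len(n)
  for (i in ids) {
    di <- d[i, ]
    di[i] <- Inf
    o <- order(di, ids)[seq_len(m)]
    idx[i, ] <- o
    dm[i, ] <- di[o]
  }
  list(idx = idx, dist = dm)
}

#' Nearest-neighbour sets of a snapshot
#'
#' For each bird, the indices of its `m` nearest other birds by Euclidean
#' distance, closest first. Exact distance ties are broken by ascending bird
#' index so results are deterministic across platforms.
#'
#' @param snapshot a [flock_snapshot()].
#' @param m number of neighbours, `1 <= m <= N-1`.
#' @return List with integer matrix `idx` (N x m, row i = neighbours of bird
#'   i, closest first) and numeric matrix `dist` of matching distances.
#' @export
knn_neighbors <- function(snapshot, m) {
  assert_snapshot(snapshot)
  knn_internal(snapshot$positions, as.integer(m))
}

# Per-node weight rows for one of the supported schemes; dm is the N x m
# closest-first distance matrix. Every row sums to 1.
weights_for_scheme <- function(dm, scheme) {
  m <- ncol(dm)
  switch(scheme,
    equal = matrix(1 / m, nrow(dm), m),
    inverse_distance = {
      if (any(dm <= 0)) stop("zero distance under inverse_distance weighting")
      w <- 1 / dm
      w / rowSums(w)
    },
    order_linear = {
      # k-th closest neighbour gets weight prop. to (m + 1 - k): the
      # hypothetical (m+1)-th neighbour would get weight 0. Normalised,
      # a_(k) = 2 (m + 1 - k) / (m (m + 1)).
      wk <- 2 * (m + 1 - seq_len(m)) / (m * (m + 1))
      matrix(wk, nrow(dm), m, byrow = TRUE)
    },
    stop("unknown weighting scheme '", scheme, "'")
  )
}

#' Edge weights for a set of nearest-neighbour distances
#'
#' Converts closest-first neighbour distances into per-edge weights under one
#' of three schemes, each normalised so every bird's weights sum to 1:
#' `equal` (1/m each, the default throughout the analysis),
#' `inverse_distance` (weight proportional to 1/distance), and
#' `order_linear` (weight decreasing linearly with neighbour rank so that a
#' hypothetical (m+1)-th neighbour would get weight 0).
#'
#' @param distances numeric matrix (N x m) of closest-first neighbour
#'   distances, as returned by [knn_neighbors()], or a single row.
#' @param scheme one of `"equal"`, `"inverse_distance"`, `"order_linear"`.
#' @return Numeric matrix of weights, same shape as `distances`, rows
#'   summing to 1.
#' @examples
#' edge_weights(matrix(c(1, 3), 1), "inverse_distance")  # 0.75, 0.25
#' @export
edge_weights <- function(distances, scheme = c("equal", "inverse_distance",
                                               "order_linear")) {
  scheme <- match.arg(scheme)
  if (is.null(dim(distances))) distances <- matrix(distances, nrow = 1L)
  weights_for_scheme(distances, scheme)
}

#' Build an m-nearest-neighbour sensing graph
#'
#' Constructs the directed, weighted interaction network in which every bird
#' senses its `m` nearest neighbours, with edge weights per `scheme` (see
#' [edge_weights()]).
#'
#' @inheritParams knn_neighbors
#' @param scheme edge-weighting scheme; the default `"equal"` gives every
#'   neighbour weight 1/m.
#' @return Object of class `sensing_graph`: list with `n_nodes`, `m`,
#'   `neighbors` (N x m integer matrix, closest first), `distances`,
#'   `weights`, `scheme`, `snapshot_id`.
#' @export
sensing_graph <- function(snapshot, m,
                          scheme = c("equal", "inverse_distance",
                                     "order_linear")) {
  assert_snapshot(snapshot)
  scheme <- match.arg(scheme)
  m <- as.integer(m)
  kn <- knn_internal(snapshot$positions, m)
  new_sensing_graph(kn$idx, kn$dist, scheme, snapshot$snapshot_id)
}

new_sensing_graph <- function(idx, dm, scheme, snapshot_id = "snapshot") {
  structure(
    list(n_nodes = nrow(idx), m = ncol(idx), neighbors = idx,
         distances = dm, weights = weights_for_scheme(dm, scheme),
         scheme = scheme, snapshot_id = snapshot_id),
    class = "sensing_graph"
  )
}

#' @export
print.sensing_graph <- function(x, ...) {
  cat("<sensing_graph> '", x$snapshot_id, "': N = ", x$n_nodes,
      ", m = ", x$m, ", scheme = ", x$scheme, "\n", sep = "")
  invisible(x)
}

#' Graph Laplacian of a sensing graph
#'
#' @param graph a [sensing_graph()].
#' @return Dense N x N Laplacian matrix L with off-diagonal entries
#'   \eqn{-a_{ij}} and diagonal entries equal to each node's total outgoing
#'   weight (1 under the sum-to-one normalisation); every row sums to 0.
#' @export
graph_laplacian <- function(graph) {
  n <- graph$n_nodes
  L <- matrix(0, n, n)
  ii <- rep.int(seq_len(n), ncol(graph$neighbors))
  L[cbind(ii, as.vector(graph$neighbors))] <- -as.vector(graph$weights)
  diag(L) <- rowSums(graph$weights)
  L
}

#' Orthonormal projector onto the disagreement subspace
#'
#' Returns the (N-1) x N matrix Q whose rows form an orthonormal basis of the
#' subspace orthogonal to the all-ones consensus direction. Built from a
#' Householder reflection mapping the first coordinate axis onto the
#' normalised all-ones vector, so the result is deterministic; any valid Q
#' yields the same H2 norm (orthogonal-similarity invariance).
#'
#' @param n number of nodes, `n >= 2`.
#' @return Numeric matrix Q with `Q %*% t(Q) = I` and `Q %*% rep(1, n) = 0`.
#' @export
consensus_projector <- function(n) {
  if (n < 2L) stop("need at least 2 nodes for a disagreement subspace")
  v <- rep(1 / sqrt(n), n)
  v[1L] <- v[1L] - 1               # v = u - e1, H = I - 2 v v' / |v|^2
  H <- diag(n) - (2 / sum(v^2)) * tcrossprod(v)
  H[-1L, , drop = FALSE]
}

#' Laplacian system: L, projector Q and reduced Laplacian
#'
#' Bundles a Laplacian with the orthonormal disagreement projector Q and the
#' reduced Laplacian \eqn{\bar L = Q L Q^T}, the generator of the
#' disagreement dynamics \eqn{\dot y = -\bar L y + Q \xi}.
#'
#' @param L square Laplacian matrix (rows summing to 0), or pass a
#'   [sensing_graph()] to [build_laplacian()].
#' @param Q optional projector with orthonormal rows spanning the complement
#'   of the all-ones direction; defaults to [consensus_projector()].
#' @return Object of class `laplacian_system`: list with `L`, `Q`,
#'   `L_reduced`, `n_nodes`.
#' @export
laplacian_system <- function(L, Q = NULL) {
  L <- as.matrix(L)
  n <- nrow(L)
  if (ncol(L) != n) stop("L must be square")
  if (is.null(Q)) Q <- consensus_projector(n)
  structure(
    list(L = L, Q = Q, L_reduced = Q %*% L %*% t(Q), n_nodes = n),
    class = "laplacian_system"
  )
}

#' @rdname laplacian_system
#' @param graph a [sensing_graph()].
#' @export
build_laplacian <- function(graph) {
  sys <- laplacian_system(graph_laplacian(graph))
  sys$snapshot_id <- graph$snapshot_id
  sys
}

#' @export
print.laplacian_system <- function(x, ...) {
  cat("<laplacian_system> N = ", x$n_nodes, "\n", sep = "")
  invisible(x)
}

# SCC condensation sink count for a directed edge list (two-column integer
# matrix, i -> j).
count_sink_components <- function(edges, n_nodes) {
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (igraph::vcount(g) < n_nodes)
    g <- igraph::add_vertices(g, n_nodes - igraph::vcount(g))
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  cross <- memb[edges[, 1L]] != memb[edges[, 2L]]
  comp$no - length(unique(memb[edges[cross, 1L]]))
}

#' Can the flock reach consensus on this graph?
#'
#' Consensus under noise-free dynamics is achievable iff some node is
#' reachable from every node along directed sensing edges — equivalently,
#' the strongly-connected-component condensation of the graph has exactly
#' one sink component, equivalently the reduced Laplacian is Hurwitz stable
#' in the \eqn{-\bar L} convention (see [is_hurwitz_stable()]).
#'
#' @param graph a [sensing_graph()], or a square matrix interpreted as a
#'   weighted adjacency matrix (entry `[i, j] > 0` means an edge i -> j;
#'   the diagonal is ignored).
#' @return `TRUE` or `FALSE`.
#' @export
is_consensus_feasible <- function(graph) {
  if (inherits(graph, "sensing_graph")) {
    n <- graph$n_nodes
    edges <- cbind(rep.int(seq_len(n), ncol(graph$neighbors)),
                   as.vector(graph$neighbors))
  } else if (is.matrix(graph)) {
    n <- nrow(graph)
    a <- graph
    diag(a) <- 0
    edges <- which(a > 0, arr.ind = TRUE)
    if (nrow(edges) == 0L) return(n == 1L)
  } else {
    stop("expected a sensing_graph or an adjacency matrix")
  }
  count_sink_components(edges, n) == 1L
}

#' Spectral (Hurwitz) feasibility test
#'
#' Checks that every eigenvalue of the reduced Laplacian has real part
#' greater than a relative tolerance, i.e. that \eqn{-\bar L} is Hurwitz and
#' the disagreement dynamics converge to a stationary distribution. Agrees
#' with the graph-theoretic [is_consensus_feasible()] test.
#'
#' @param system a [laplacian_system()].
#' @param tol_rel spectral tolerance relative to the largest eigenvalue
#'   magnitude.
#' @return `TRUE` or `FALSE`.
#' @export
is_hurwitz_stable <- function(system, tol_rel = 1e-9) {
  ev <- eigen(system$L_reduced, only.values = TRUE)$values
  scale <- max(abs(ev))
  if (scale == 0) return(FALSE)
  min(Re(ev)) > tol_rel * scale
}
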