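#' Convert edge weights to traversal lengths
#'
#' Shortest-path computations need a length (cost) per edge. The dominant
#' connectome convention, used here for all weightings, is the reciprocal:
#' stronger edges are shorter, `length = 1/weight`, absent edges are
#' infinite; binary edges get unit length. For FL-weighted networks an
#' alternative reading treats the mean tract length itself as the cost
#' (`convention = "direct"`).
#'
#' @param m A `connectome_matrix` (or plain non-negative symmetric matrix).
#' @param convention `"reciprocal"` (default) or `"direct"`.
#' @return Symmetric matrix of edge lengths, `Inf` where no edge, 0 diagonal.
#' @export
edge_lengths <- function(m, convention = c("reciprocal", "direct")) {
  convention <- match.arg(convention)
  w <- unclass(m)
  len <- matrix(Inf, nrow(w), ncol(w), dimnames = dimnames(w))
  pos <- w > 0
  len[pos] <- if (convention == "reciprocal") 1 / w[pos] else w[pos]
  diag(len) <- 0
  len
}

graph_from_lengths <- function(lengths) {
  n <- nrow(lengths)
  idx <- which(upper.tri(lengths) & is.finite(lengths))
  rows <- ((idx - 1L) %% n) + 1L
  cols <- ((idx - 1L) %/% n) + 1L
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(idx)) {
    g <- igraph::add_edges(g, rbind(rows, cols))
    igraph::E(g)$weight <- lengths[idx]
  }
  g
}

#' All-pairs shortest-path distances
#'
#' Exact Dijkstra distances (via igraph) from every node over a
#' non-negative length matrix; unreachable pairs are `Inf`.
#'
#' @param lengths Length matrix from [edge_lengths()].
#' @return Symmetric distance matrix with zero diagonal.
#' @export
shortest_path_lengths <- function(lengths) {
  lengths <- as.matrix(lengths)
  if (any(lengths < 0)) stop("edge lengths must be non-negative", call. = FALSE)
  g <- graph_from_lengths(lengths)
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- dimnames(lengths)
  d
}

#' Distance matrix of a connectome
#' @inheritParams edge_lengths
#' @return Symmetric shortest-path distance matrix.
#' @export
distance_matrix <- function(m, convention = "reciprocal") {
  shortest_path_lengths(edge_lengths(m, convention))
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over all ordered node pairs,
#' `E_glob = (1/(N(N-1))) * sum_{i != j} 1/d_ij`; unreachable pairs
#' contribute 0. Equals 1 exactly for a complete binary graph.
#'
#' @param d Distance matrix (N >= 2).
#' @return Scalar in `[0, 1]` for binary graphs.
#' @export
global_efficiency <- function(d) {
  n <- nrow(d)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic (shortest) path length
#'
#' Mean shortest-path distance over *reachable* ordered pairs (`Inf` when
#' no pair is reachable); the disconnected share is available from
#' [unreachable_fraction()]. Averaging reachable pairs only keeps the
#' metric finite and comparable across subjects with occasional missing
#' edges. `method = "harmonic"` instead returns the harmonic mean over all
#' pairs (the reciprocal of global efficiency).
#'
#' @param d Distance matrix (N >= 2).
#' @param method `"reachable-mean"` (default) or `"harmonic"`.
#' @return Scalar > 0 (>= 1 for binary graphs) or `Inf`.
#' @export
characteristic_path_length <- function(d, method = c("reachable-mean", "harmonic")) {
  method <- match.arg(method)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  if (method == "harmonic") {
    eg <- global_efficiency(d)
    return(if (eg > 0) 1 / eg else Inf)
  }
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  if (!length(finite)) Inf else mean(finite)
}

#' Fraction of unreachable ordered node pairs
#' @param d Distance matrix.
#' @return Scalar in `[0, 1]`.
#' @export
unreachable_fraction <- function(d) {
  off <- d[row(d) != col(d)]
  mean(!is.finite(off))
}

#' Nodal efficiency
#'
#' `E_nodal(i) = (1/(N-1)) * sum_{j != i} 1/d_ij`: a node's mean inverse
#' distance to every other node; in `[0, 1]` for binary graphs.
#'
#' @param d Distance matrix (N >= 2).
#' @param i Optional node index or id; default all nodes.
#' @return Named numeric vector (or scalar when `i` is given).
#' @export
nodal_efficiency <- function(d, i = NULL) {
  n <- nrow(d)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  en <- rowSums(inv) / (n - 1)
  names(en) <- rownames(d)
  if (is.null(i)) en else en[[i]]
}

#' Nodal shortest path length
#'
#' Mean distance from node `i` to every reachable other node (`Inf` for an
#' isolated node).
#'
#' @inheritParams nodal_efficiency
#' @return Named numeric vector (or scalar).
#' @export
nodal_path_length <- function(d, i = NULL) {
  n <- nrow(d)
  lp <- vapply(seq_len(n), function(k) {
    v <- d[k, -k]
    v <- v[is.finite(v)]
    if (!length(v)) Inf else mean(v)
  }, numeric(1))
  names(lp) <- rownames(d)
  if (is.null(i)) lp else lp[[i]]
}

#' Degree centrality
#'
#' Binary networks: number of incident edges; weighted networks: node
#' strength (sum of incident weights).
#'
#' @param m A `connectome_matrix` (or non-negative symmetric matrix).
#' @param i Optional node index or id.
#' @return Named numeric vector (or scalar).
#' @export
degree_centrality <- function(m, i = NULL) {
  w <- unclass(m)
  dc <- rowSums(w)
  names(dc) <- rownames(w)
  if (is.null(i)) dc else dc[[i]]
}

#' Betweenness centrality
#'
#' Fraction of all-pairs shortest paths (under reciprocal-weight lengths)
#' passing through each node, with equal-length multiplicities shared
#' fractionally, normalised by `(N-1)(N-2)/2` so values lie in `[0, 1]`.
#'
#' @inheritParams edge_lengths
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(m, convention = "reciprocal") {
  lengths <- edge_lengths(m, convention)
  g <- graph_from_lengths(lengths)
  n <- nrow(lengths)
  bc <- igraph::betweenness(g, directed = FALSE)
  bc <- bc / ((n - 1) * (n - 2) / 2)
  names(bc) <- rownames(lengths)
  bc
}

#' Clustering coefficient
#'
#' Binary networks: triangle density among each node's neighbours. Weighted
#' networks: the Onnela geometric-mean form, with weights scaled by the
#' maximum weight. Nodes with degree < 2 get 0.
#'
#' @param m A `connectome_matrix` (or non-negative symmetric matrix).
#' @return Named numeric vector; the network mean `C_p` is `mean()` of it.
#' @export
clustering_coefficient <- function(m) {
  w <- unclass(m)
  n <- nrow(w)
  a <- (w > 0) * 1
  k <- rowSums(a)
  denom <- k * (k - 1)
  if (max(w) > 0 && !all(w %in% c(0, 1))) {
    wn <- (w / max(w))^(1 / 3)
    tri <- diag(wn %*% wn %*% wn)
  } else {
    tri <- diag(a %*% a %*% a)
  }
  cc <- ifelse(denom > 0, tri / denom, 0)
  names(cc) <- rownames(w)
  cc
}

#' Local efficiency
#'
#' `E_loc(i)` is the global efficiency of the subgraph induced on the
#' neighbours of `i` (0 when fewer than 2 neighbours).
#'
#' @inheritParams clustering_coefficient
#' @param convention Length convention for weighted subgraph distances.
#' @return Named numeric vector; the network mean is `mean()` of it.
#' @export
local_efficiency <- function(m, convention = "reciprocal") {
  w <- unclass(m)
  n <- nrow(w)
  le <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- w[nb, nb, drop = FALSE]
    global_efficiency(shortest_path_lengths(edge_lengths(sub, convention)))
  }, numeric(1))
  names(le) <- rownames(w)
  le
}
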