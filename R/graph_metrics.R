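#' @name graph-metrics
#' @title Weighted graph measures of integration, segregation and nodal
#'   influence
#' @description
#' All path-based measures interpret connection weights as capacities and
#' travel along connection lengths `1/w` (stronger connections are shorter).
#' The integration and segregation measures (`characteristic_path_length()`,
#' `global_efficiency()`, `clustering_coefficient()`) support a total-weight
#' normalization mode (the default), in which all weights are divided by the
#' network's total weight before the measure is computed; this makes the
#' measures invariant to global rescaling of the weights and therefore
#' comparable across subjects. Degree and strength are always computed on
#' the stored (thresholded) weights.
NULL

# resolve a weighted_network or bare matrix to a weight matrix under the
# selected normalization mode
metric_weights <- function(net, normalization = c("total", "none")) {
  normalization <- match.arg(normalization)
  w <- if (inherits(net, "weighted_network")) net$weights else as.matrix(net)
  if (normalization == "total") {
    tw <- sum(w) / 2
    if (tw > 0) w <- w / tw
  }
  w
}

#' Connection-length matrix
#'
#' Converts a weighted connection matrix to a connection-length matrix:
#' `length(i, j) = 1 / weight(i, j)` for nonzero weights, `Inf` for absent
#' edges, and 0 on the diagonal.
#'
#' @param net a [weighted_network()] or symmetric weight matrix.
#' @param normalization `"total"` (divide weights by the total weight sum
#'   first) or `"none"`.
#' @return A numeric length matrix.
#' @export
connection_length_matrix <- function(net, normalization = c("total",
                                                            "none")) {
  w <- metric_weights(net, normalization)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  len
}

# all-pairs shortest path lengths on the 1/weight length matrix
shortest_path_lengths <- function(net, normalization = "total") {
  w <- metric_weights(net, normalization)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    d <- matrix(Inf, nrow(w), ncol(w), dimnames = dimnames(w))
    diag(d) <- 0
    return(d)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

#' Characteristic path length
#'
#' The average shortest path between all pairs of nodes, computed on the
#' connection-length matrix. Pairs with no connecting path are excluded
#' from the mean; their count is attached as attribute
#' `"disconnected_pairs"` (unordered pairs).
#'
#' @inheritParams connection_length_matrix
#' @return Scalar path length with attribute `disconnected_pairs`.
#' @export
characteristic_path_length <- function(net, normalization = c("total",
                                                              "none")) {
  normalization <- match.arg(normalization)
  w <- metric_weights(net, normalization)
  if (nrow(w) < 2) stop("need at least 2 nodes")
  if (all(w == 0)) stop("network has no edges")
  d <- shortest_path_lengths(w, normalization = "none")
  dv <- d[upper.tri(d)]
  finite <- is.finite(dv)
  structure(mean(dv[finite]),
            disconnected_pairs = sum(!finite))
}

#' Global efficiency
#'
#' The average inverse shortest path length over all pairs of nodes, with
#' disconnected pairs contributing 0.
#'
#' @inheritParams connection_length_matrix
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(net, normalization = c("total", "none")) {
  normalization <- match.arg(normalization)
  w <- metric_weights(net, normalization)
  if (nrow(w) < 2) stop("need at least 2 nodes")
  if (all(w == 0)) return(0)
  d <- shortest_path_lengths(w, normalization = "none")
  dv <- d[upper.tri(d)]
  mean(ifelse(is.finite(dv), 1 / dv, 0))
}

#' Weighted clustering coefficient (Onnela formulation)
#'
#' Per-node likelihood of neighboring nodes to form closed triangles,
#' weighted by the geometric mean of triangle edge weights after rescaling
#' all weights by their maximum:
#' `C_i = sum_jh (w'_ij w'_ih w'_jh)^(1/3) / (k_i (k_i - 1))` with
#' `w' = w / max(w)`. Nodes with degree below 2 get 0. Because of the
#' max-rescale the measure is invariant to global weight scaling, so the
#' normalization mode does not change its value; the argument is kept for
#' interface symmetry with the path-based measures.
#'
#' @inheritParams connection_length_matrix
#' @return Named per-node vector of clustering coefficients.
#' @export
clustering_coefficient <- function(net, normalization = c("total",
                                                          "none")) {
  w <- metric_weights(net, normalization)
  if (max(w) == 0) return(stats::setNames(rep(0, nrow(w)), rownames(w)))
  a <- (w / max(w))^(1 / 3)
  k <- rowSums(w > 0)
  tri <- diag(a %*% a %*% a)
  c_i <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  stats::setNames(c_i, rownames(w))
}

#' Nodal degree
#'
#' Number of links connected to each node.
#'
#' @param net a [weighted_network()] or weight matrix.
#' @return Named integer vector.
#' @export
nodal_degree <- function(net) {
  w <- if (inherits(net, "weighted_network")) net$weights else as.matrix(net)
  stats::setNames(as.integer(rowSums(w > 0)), rownames(w))
}

#' Nodal strength
#'
#' Sum of weights of links connected to each node.
#'
#' @param net a [weighted_network()] or weight matrix.
#' @return Named numeric vector.
#' @export
nodal_strength <- function(net) {
  w <- if (inherits(net, "weighted_network")) net$weights else as.matrix(net)
  stats::setNames(rowSums(w), rownames(w))
}

#' Betweenness centrality
#'
#' Fraction of all shortest paths in the network that pass through each
#' node, computed on the connection-length matrix (`1/weight`), with
#' equal-length path multiplicity shared fractionally, and normalized by
#' the factor `(n - 1)(n - 2)`. Unordered node pairs are counted once, so
#' values lie in `[0, 1]` (at most 0.5 for an interior node of a path
#' graph's center analogue; exactly 0 for every node of a complete
#' unit-weight graph).
#'
#' @param net a [weighted_network()] or weight matrix.
#' @return Named numeric vector of normalized betweenness values.
#' @export
betweenness_centrality <- function(net) {
  w <- if (inherits(net, "weighted_network")) net$weights else as.matrix(net)
  n <- nrow(w)
  if (n < 3) stop("betweenness needs at least 3 nodes")
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  raw <- if (igraph::ecount(g) == 0) rep(0, n)
  else igraph::betweenness(g, directed = FALSE,
                           weights = 1 / igraph::E(g)$weight)
  stats::setNames(raw / ((n - 1) * (n - 2)), rownames(w))
}

#' Nodal metric table
#'
#' Per-node degree, strength, betweenness centrality and (when a partition
#' is supplied) participation coefficient for one network.
#'
#' @param net a [weighted_network()].
#' @param partition optional [louvain_partition()] (or named module vector)
#'   for participation coefficients.
#' @return A data.frame with one row per node.
#' @export
nodal_metrics <- function(net, partition = NULL) {
  out <- data.frame(node = net$atlas$label,
                    degree = as.numeric(nodal_degree(net)),
                    strength = as.numeric(nodal_strength(net)),
                    betweenness = as.numeric(betweenness_centrality(net)))
  if (!is.null(partition))
    out$participation <-
      as.numeric(participation_coefficient(net, partition))
  out
}

#' Global metric table
#'
#' Characteristic path length, global efficiency and mean clustering
#' coefficient for one network, under one normalization mode. The mode is
#' recorded in the output so results are always labeled with the
#' normalization they used.
#'
#' @inheritParams connection_length_matrix
#' @return A one-row data.frame.
#' @export
global_metrics <- function(net, normalization = c("total", "none")) {
  normalization <- match.arg(normalization)
  cpl <- characteristic_path_length(net, normalization)
  data.frame(char_path_length = as.numeric(cpl),
             global_efficiency = global_efficiency(net, normalization),
             clustering_coefficient =
               mean(clustering_coefficient(net, normalization)),
             disconnected_pairs = attr(cpl, "disconnected_pairs"),
             normalization = normalization)
}
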