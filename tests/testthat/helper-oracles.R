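# Fixtures and independent brute-force oracles used across the suite.

# tiny atlas with unit voxel counts so normalization is the identity
toy_atlas <- function(n, voxels = rep(1L, n)) {
  atlas_spec(sprintf("R%02d", seq_len(n)),
             rep(c("L", "R"), length.out = n), voxels)
}

# weighted_network straight from a symmetric matrix
toy_net <- function(w, voxels = NULL) {
  n <- nrow(w)
  if (is.null(voxels)) voxels <- rep(1L, n)
  weighted_network(w, toy_atlas(n, voxels))
}

# symmetric weight matrix from an edge list (i, j, w)
edge_matrix <- function(n, edges) {
  w <- matrix(0, n, n)
  for (e in edges) {
    w[e[1], e[2]] <- e[3]
    w[e[2], e[1]] <- e[3]
  }
  w
}

# random connected weighted graph (retries until connected)
random_connected_graph <- function(n, p = 0.6) {
  repeat {
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w))
    on <- runif(length(ut)) < p
    w[ut[on]] <- runif(sum(on), 0.2, 2)
    w <- w + t(w)
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    if (igraph::is_connected(g) && sum(on) > 0) return(w)
  }
}

# Brute-force all-pairs analysis by exhaustive simple-path enumeration on
# the 1/weight length matrix. Returns shortest-path distances and raw
# betweenness pair-dependencies (unordered pairs, fractional sharing).
brute_paths <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  dep <- rep(0, n)
  for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
    paths <- list()
    walk <- function(node, visited, d) {
      if (node == t) {
        paths[[length(paths) + 1L]] <<- list(d = d, via = visited)
        return()
      }
      for (nb in which(w[node, ] > 0))
        if (!(nb %in% visited))
          walk(nb, c(visited, nb), d + len[node, nb])
    }
    walk(s, s, 0)
    if (!length(paths)) next
    ds <- vapply(paths, `[[`, 0, "d")
    dmin <- min(ds)
    dist[s, t] <- dist[t, s] <- dmin
    sp <- paths[abs(ds - dmin) < 1e-12]
    for (pp in sp) {
      interior <- setdiff(pp$via, c(s, t))
      dep[interior] <- dep[interior] + 1 / length(sp)
    }
  }
  list(dist = dist, betweenness_raw = dep)
}

brute_cpl <- function(w) {
  d <- brute_paths(w)$dist[upper.tri(w)]
  mean(d[is.finite(d)])
}

brute_efficiency <- function(w) {
  d <- brute_paths(w)$dist[upper.tri(w)]
  mean(ifelse(is.finite(d), 1 / d, 0))
}

brute_betweenness <- function(w) {
  n <- nrow(w)
  brute_paths(w)$betweenness_raw / ((n - 1) * (n - 2))
}

# participation coefficient by direct per-node summation
brute_participation <- function(w, modules) {
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k == 0) return(0)
    1 - sum((table(modules[nb]) / k)^2)
  }, 0)
}
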