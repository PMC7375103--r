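#' Multi-iteration consensus Louvain community detection
#'
#' Runs the weighted Louvain modularity-maximization algorithm
#' `n_iterations` times (each iteration on an independently permuted node
#' order with its own RNG substream), then derives a consensus partition by
#' standard consensus clustering: build the node-pair agreement matrix over
#' iterations, keep pairs that co-occur in at least half of them, re-cluster
#' the agreement matrix with Louvain, and repeat until all iterations
#' agree. Module ids are relabeled in descending module size. The returned
#' modularity `Q` is always recomputed on the original network with
#' [modularity_q()]; the single best per-iteration partition (maximum Q) is
#' retained alongside for comparison.
#'
#' @param net a [weighted_network()] (or symmetric weight matrix) with at
#'   least one edge.
#' @param n_iterations number of Louvain iterations (default 100).
#' @param seed optional RNG seed for reproducible consensus.
#' @return An object of class `louvain_partition`: list with `assignment`
#'   (named node -> module id), `q`, `n_modules`, `iteration_qs`,
#'   `best_iteration` (max-Q single-run assignment), `method`,
#'   `n_iterations` and `seed`.
#' @export
louvain_partition <- function(net, n_iterations = 100, seed = NULL) {
  w <- if (inherits(net, "weighted_network")) net$weights else as.matrix(net)
  if (all(w == 0)) stop("cannot partition an edgeless network")
  if (!is.null(seed)) set.seed(seed)
  labs <- rownames(w)
  memb <- louvain_runs(w, n_iterations)
  qs <- apply(memb, 2, function(m) modularity_q(w, m))

  consensus <- memb
  rounds <- 0L
  repeat {
    if (rounds >= 20L) {
      warning("consensus did not stabilize after 20 rounds; ",
              "using the current majority partition")
      break
    }
    rounds <- rounds + 1L
    agree <- agreement_matrix(consensus)
    if (all_columns_identical(consensus)) break
    cons_w <- agree
    cons_w[agree < 0.5] <- 0
    diag(cons_w) <- 0
    if (all(cons_w == 0)) {  # no stable pairs: every node its own module
      consensus <- matrix(seq_len(nrow(w)), nrow(w), 1)
      break
    }
    consensus <- louvain_runs(cons_w, n_iterations)
  }
  assignment <- relabel_by_size(consensus[, 1])
  names(assignment) <- labs
  best <- relabel_by_size(memb[, which.max(qs)])
  names(best) <- labs
  structure(list(assignment = assignment,
                 q = modularity_q(w, assignment),
                 n_modules = max(assignment),
                 iteration_qs = qs,
                 best_iteration = best,
                 method = "consensus-louvain",
                 n_iterations = n_iterations,
                 seed = seed),
            class = "louvain_partition")
}

#' @export
print.louvain_partition <- function(x, ...) {
  cat("<louvain_partition>", x$n_modules, "modules, Q =",
      sprintf("%.4f", x$q), sprintf("(%s, %d iterations)", x$method,
                                    x$n_iterations), "\n")
  print(table(module = x$assignment))
  invisible(x)
}

# n_iterations Louvain runs on a weight matrix, each with a random vertex
# permutation; returns an n x n_iterations membership matrix
louvain_runs <- function(w, n_iterations) {
  n <- nrow(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- matrix(NA_integer_, n, n_iterations)
  for (it in seq_len(n_iterations)) {
    perm <- sample.int(n)
    gp <- igraph::permute(g, perm)
    m <- igraph::membership(igraph::cluster_louvain(gp))
    memb[, it] <- as.integer(m[perm])
  }
  memb
}

# fraction of iterations in which each node pair shares a community
agreement_matrix <- function(memb) {
  acc <- matrix(0, nrow(memb), nrow(memb))
  for (it in seq_len(ncol(memb))) {
    ind <- outer(memb[, it], memb[, it], "==")
    acc <- acc + ind
  }
  acc / ncol(memb)
}

all_columns_identical <- function(memb) {
  if (ncol(memb) == 1L) return(TRUE)
  ref <- memb[, 1]
  all(apply(memb[, -1, drop = FALSE], 2, function(m)
    all(outer(m, m, "==") == outer(ref, ref, "=="))))
}

relabel_by_size <- function(m) {
  sizes <- table(m)
  new_id <- stats::setNames(rank(-as.numeric(sizes), ties.method = "first"),
                            names(sizes))
  as.integer(new_id[as.character(m)])
}

#' Weighted Newman-Girvan modularity
#'
#' `Q = sum_c [ W_c / W - (S_c / 2W)^2 ]` over communities `c`, where `W_c`
#' is the total within-community weight, `S_c` the total strength of the
#' community's nodes and `W` the total edge weight of the network. `Q = 0`
#' for the trivial one-block partition; `Q <= 1` always.
#'
#' @param net a [weighted_network()] or symmetric weight matrix.
#' @param assignment named (or atlas-ordered) node -> community vector
#'   covering every node.
#' @return Scalar modularity.
#' @export
modularity_q <- function(net, assignment) {
  w <- if (inherits(net, "weighted_network")) net$weights else as.matrix(net)
  if (inherits(assignment, "louvain_partition"))
    assignment <- assignment$assignment
  if (length(assignment) != nrow(w) || anyNA(assignment))
    stop("assignment must cover every node")
  if (!is.null(names(assignment)) && !is.null(rownames(w)))
    assignment <- assignment[rownames(w)]
  if (anyNA(assignment)) stop("assignment must cover every node")
  total2 <- sum(w)  # 2W: each edge counted in both directions
  if (total2 == 0) stop("modularity of an edgeless network is undefined")
  q <- 0
  for (cm in unique(assignment)) {
    idx <- which(assignment == cm)
    q <- q + sum(w[idx, idx]) / total2 - (sum(w[idx, ]) / total2)^2
  }
  q
}

#' Participation coefficient
#'
#' `PI_i = 1 - sum_m (kappa_im / k_i)^2`, where `kappa_im` is the number of
#' node i's edges into module m and `k_i` its degree (binary counts by
#' default; set `weighted = TRUE` to use strength fractions). Nodes with no
#' edges get `PI = 0`. Low PI marks within-module (provincial) connectivity;
#' intermediate PI marks between-module (connector) connectivity.
#'
#' @param net a [weighted_network()] or weight matrix.
#' @param partition a [louvain_partition()] or named module vector.
#' @param weighted use edge weights instead of binary edge counts.
#' @return Named per-node vector of PI values in `[0, 1]`.
#' @export
participation_coefficient <- function(net, partition, weighted = FALSE) {
  w <- if (inherits(net, "weighted_network")) net$weights else as.matrix(net)
  assign <- if (inherits(partition, "louvain_partition"))
    partition$assignment else partition
  if (length(assign) != nrow(w)) stop("partition must cover every node")
  if (!is.null(names(assign)) && !is.null(rownames(w)))
    assign <- assign[rownames(w)]
  a <- if (weighted) w else (w > 0) + 0
  k <- rowSums(a)
  # kappa[i, m]: node i's connection mass into module m
  kappa <- t(rowsum(t(a), group = assign))
  pi_i <- ifelse(k > 0, 1 - rowSums((kappa / pmax(k, 1))^2), 0)
  stats::setNames(pi_i, rownames(w))
}

#' Classify hubs by participation coefficient
#'
#' Provincial hubs link nodes within a module (`PI <= 0.3`); connector hubs
#' link nodes between modules (`0.3 < PI <= 0.75`); values above 0.75 are
#' unclassified. This follows the standard participation-coefficient
#' convention for hub taxonomy. `convention = "inverted"` swaps the
#' provincial and connector bands for comparison with sources that state
#' the ranges the other way around.
#'
#' @param pi participation coefficient(s) in `[0, 1]`.
#' @param convention `"standard"` (default) or `"inverted"`.
#' @return Character vector: `"provincial"`, `"connector"` or
#'   `"unclassified"`.
#' @export
classify_hub <- function(pi, convention = c("standard", "inverted")) {
  convention <- match.arg(convention)
  if (any(pi < 0 | pi > 1)) stop("PI must lie in [0, 1]")
  low <- ifelse(pi <= 0.3, TRUE, FALSE)
  mid <- pi > 0.3 & pi <= 0.75
  out <- rep("unclassified", length(pi))
  if (convention == "standard") {
    out[low] <- "provincial"
    out[mid] <- "connector"
  } else {
    out[low] <- "connector"
    out[mid] <- "provincial"
  }
  out
}

#' Identify network hubs on a group-averaged network
#'
#' A node is a degree-basis hub if its nodal degree is at least one
#' standard deviation above the network's mean degree, and a strength-basis
#' hub analogously for nodal strength; the two bases are evaluated
#' independently, so a node may be a hub on both. The SD is the sample SD
#' over the nodal values; when the SD is zero (all values equal) no node is
#' a hub. Each hub carries its module, participation coefficient and
#' provincial/connector class.
#'
#' @param net a group-averaged, thresholded [weighted_network()].
#' @param partition a [louvain_partition()] of `net`.
#' @param convention hub-class convention passed to [classify_hub()].
#' @return A data.frame with columns `node`, `basis`, `value`, `module`,
#'   `participation`, `klass`.
#' @export
identify_hubs <- function(net, partition,
                          convention = c("standard", "inverted")) {
  convention <- match.arg(convention)
  assign <- if (inherits(partition, "louvain_partition"))
    partition$assignment else partition
  pi_i <- participation_coefficient(net, partition)
  out <- list()
  for (basis in c("degree", "strength")) {
    vals <- if (basis == "degree") nodal_degree(net) else nodal_strength(net)
    s <- stats::sd(vals)
    if (is.na(s) || s == 0) next
    thr <- mean(vals) + s
    hub_idx <- which(vals >= thr)
    if (!length(hub_idx)) next
    labs <- names(vals)[hub_idx]
    out[[basis]] <- data.frame(
      node = labs, basis = basis, value = as.numeric(vals[hub_idx]),
      module = as.integer(assign[labs]),
      participation = as.numeric(pi_i[labs]),
      klass = classify_hub(as.numeric(pi_i[labs]), convention))
  }
  if (!length(out))
    return(data.frame(node = character(), basis = character(),
                      value = numeric(), module = integer(),
                      participation = numeric(), klass = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# all permutations of seq_len(k), as a list (k <= 8 kept tractable)
all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L))
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Match modules between two partitions
#'
#' Finds the one-to-one module correspondence maximizing the total number
#' of shared nodes on the contingency table of the two assignments (optimal
#' assignment by exhaustive search over pairings; module counts in
#' community analyses are small). Surplus modules on either side are
#' reported as unmatched.
#'
#' @param partition_a,partition_b [louvain_partition()]s (or named module
#'   vectors) over the same atlas.
#' @return A list with `pairs` (data.frame `module_a`, `module_b`,
#'   `overlap`), `unmatched_a`, `unmatched_b`.
#' @export
match_modules <- function(partition_a, partition_b) {
  a <- if (inherits(partition_a, "louvain_partition"))
    partition_a$assignment else partition_a
  b <- if (inherits(partition_b, "louvain_partition"))
    partition_b$assignment else partition_b
  if (!identical(sort(names(a)), sort(names(b))))
    stop("partitions must cover the same nodes")
  b <- b[names(a)]
  tab <- table(a, b)
  ka <- nrow(tab); kb <- ncol(tab)
  k <- max(ka, kb)
  padded <- matrix(0, k, k)
  padded[seq_len(ka), seq_len(kb)] <- tab
  if (k <= 8L) {
    best <- NULL; best_score <- -1
    for (p in all_perms(k)) {
      score <- sum(padded[cbind(seq_len(k), p)])
      if (score > best_score) { best_score <- score; best <- p }
    }
  } else {
    # many modules: greedy descent on overlap (exact search is factorial)
    best <- rep(NA_integer_, k)
    remaining <- seq_len(k)
    for (i in order(-apply(padded, 1, max))) {
      j <- remaining[which.max(padded[i, remaining])]
      best[i] <- j
      remaining <- setdiff(remaining, j)
    }
  }
  pairs <- data.frame(module_a = as.integer(rownames(tab))[seq_len(k)],
                      module_b = as.integer(colnames(tab))[best],
                      overlap = padded[cbind(seq_len(k), best)])
  real <- !is.na(pairs$module_a) & !is.na(pairs$module_b)
  list(pairs = pairs[real, , drop = FALSE],
       unmatched_a = pairs$module_a[is.na(pairs$module_b)],
       unmatched_b = pairs$module_b[is.na(pairs$module_a)])
}

#' Module migration between two group-level partitions
#'
#' After matching modules with [match_modules()], reports the signed
#' percent size change of each matched module
#' (`(size_b - size_a) / size_a * 100`) and the list of nodes that migrated
#' from one community to another between the two partitions.
#'
#' @inheritParams match_modules
#' @return A list with `module_size_changes` (data.frame `module_a`,
#'   `module_b`, `size_a`, `size_b`, `percent_change`) and `migrations`
#'   (data.frame `node`, `from`, `to`, in partition-A module ids).
#' @export
module_migration <- function(partition_a, partition_b) {
  a <- if (inherits(partition_a, "louvain_partition"))
    partition_a$assignment else partition_a
  b <- if (inherits(partition_b, "louvain_partition"))
    partition_b$assignment else partition_b
  b <- b[names(a)]
  matching <- match_modules(a, b)
  pairs <- matching$pairs
  pairs$size_a <- as.integer(table(a)[as.character(pairs$module_a)])
  pairs$size_b <- as.integer(table(b)[as.character(pairs$module_b)])
  pairs$percent_change <- (pairs$size_b - pairs$size_a) /
    pairs$size_a * 100
  # express partition B in partition A's module labels
  to_a <- stats::setNames(pairs$module_a, pairs$module_b)
  b_relab <- to_a[as.character(b)]
  moved <- which(b_relab != a | is.na(b_relab))
  migrations <- data.frame(node = names(a)[moved],
                           from = as.integer(a[moved]),
                           to = as.integer(b_relab[moved]))
  list(module_size_changes = pairs[, c("module_a", "module_b", "size_a",
                                       "size_b", "percent_change")],
       migrations = migrations)
}

#' Compare hub tables of two group networks
#'
#' Set comparison by (node, basis) keys: hubs present in both tables
#' (`shared`), present only in the second (`gained`), present only in the
#' first (`lost`), and shared hubs whose provincial/connector class
#' changed (`status_changes`).
#'
#' @param hubs_a,hubs_b hub tables from [identify_hubs()] on matched group
#'   networks (A is the reference, e.g. controls).
#' @return A list of class `hub_comparison` with data.frames `shared`,
#'   `gained`, `lost` and `status_changes` (`node`, `basis`, `from_klass`,
#'   `to_klass`).
#' @export
compare_hubs <- function(hubs_a, hubs_b) {
  key_a <- paste(hubs_a$node, hubs_a$basis)
  key_b <- paste(hubs_b$node, hubs_b$basis)
  shared_keys <- intersect(key_a, key_b)
  shared <- hubs_a[key_a %in% shared_keys,
                   c("node", "basis"), drop = FALSE]
  gained <- hubs_b[!(key_b %in% key_a),
                   c("node", "basis", "value", "klass"), drop = FALSE]
  lost <- hubs_a[!(key_a %in% key_b),
                 c("node", "basis", "value", "klass"), drop = FALSE]
  sc <- merge(hubs_a[key_a %in% shared_keys,
                     c("node", "basis", "klass")],
              hubs_b[key_b %in% shared_keys,
                     c("node", "basis", "klass")],
              by = c("node", "basis"), suffixes = c("_a", "_b"))
  sc <- sc[sc$klass_a != sc$klass_b, , drop = FALSE]
  status_changes <- data.frame(node = sc$node, basis = sc$basis,
                               from_klass = sc$klass_a,
                               to_klass = sc$klass_b)
  rownames(shared) <- rownames(gained) <- rownames(lost) <- NULL
  structure(list(shared = shared, gained = gained, lost = lost,
                 status_changes = status_changes),
            class = "hub_comparison")
}

#' @export
print.hub_comparison <- function(x, ...) {
  cat("<hub_comparison>", nrow(x$shared), "shared,", nrow(x$gained),
      "gained,", nrow(x$lost), "lost,", nrow(x$status_changes),
      "status changes\n")
  invisible(x)
}
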