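#' Per-subject streamline-count matrix
#'
#' The raw output of whole-brain deterministic tractography for one subject:
#' a symmetric, non-negative integer matrix of streamline counts between all
#' pairs of atlas regions, with a zero diagonal.
#'
#' @param counts n x n integer matrix of streamline counts; row/column order
#'   must follow the atlas.
#' @param atlas an [atlas_spec()].
#' @param subject_id subject identifier.
#' @param group group label (e.g. `"controls"`).
#' @return An object of class `streamline_matrix`.
#' @export
streamline_matrix <- function(counts, atlas, subject_id = NA_character_,
                              group = NA_character_) {
  counts <- as.matrix(counts)
  n <- n_regions(atlas)
  if (!all(dim(counts) == n))
    stop("counts must be ", n, " x ", n, " to match the atlas")
  if (any(counts < 0)) stop("streamline counts must be non-negative")
  if (any(counts != round(counts))) stop("streamline counts must be integers")
  if (!isTRUE(all.equal(counts, t(counts))))
    stop("streamline counts must be symmetric")
  if (any(diag(counts) != 0)) stop("streamline counts must have zero diagonal")
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max sums
  dimnames(counts) <- list(atlas$label, atlas$label)
  structure(list(counts = counts, atlas = atlas,
                 subject_id = subject_id, group = group),
            class = "streamline_matrix")
}

#' @export
print.streamline_matrix <- function(x, ...) {
  cat("<streamline_matrix> subject:", x$subject_id,
      " group:", x$group, "\n")
  cat("  ", nrow(x$counts), "regions,",
      sum(x$counts[upper.tri(x$counts)] > 0), "nonzero edges,",
      "total streamline count", sum(x$counts) / 2, "\n")
  invisible(x)
}

#' Weighted structural network
#'
#' The unit all graph measures consume: a symmetric non-negative weighted
#' adjacency matrix with zero diagonal over an atlas, together with the
#' ordered provenance of transformations that produced it.
#'
#' @param weights n x n symmetric non-negative numeric matrix, zero diagonal.
#' @param atlas an [atlas_spec()].
#' @param provenance character vector of transformation tags applied so far.
#' @param subject_id,group optional identifiers carried through the pipeline.
#' @return An object of class `weighted_network`.
#' @export
weighted_network <- function(weights, atlas, provenance = character(),
                             subject_id = NA_character_,
                             group = NA_character_) {
  weights <- as.matrix(weights)
  n <- n_regions(atlas)
  if (!all(dim(weights) == n))
    stop("weights must be ", n, " x ", n, " to match the atlas")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-10)))
    stop("weights must be symmetric")
  if (any(diag(weights) != 0)) stop("weights must have zero diagonal")
  dimnames(weights) <- list(atlas$label, atlas$label)
  structure(list(weights = weights, atlas = atlas,
                 provenance = as.character(provenance),
                 subject_id = subject_id, group = group),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("<weighted_network>", nrow(x$weights), "regions, density",
      sprintf("%.3f", network_density(x)), "\n")
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id,
                                " group:", x$group, "\n")
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Network density
#'
#' Fraction of possible off-diagonal region pairs connected by a nonzero
#' edge: `E / (n(n-1)/2)` for an undirected network with `E` nonzero edges.
#'
#' @param net a [weighted_network()] (or a bare symmetric matrix).
#' @return density in `[0, 1]`.
#' @export
network_density <- function(net) {
  w <- if (inherits(net, "weighted_network")) net$weights else as.matrix(net)
  n <- nrow(w)
  if (n < 2) stop("density needs at least 2 nodes")
  sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2)
}

# igraph view of a weighted_network; edge attribute "weight" holds the
# stored connection weight (not the length).
as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# Upper-triangle edge list ordered deterministically for threshold/prune:
# ascending weight, ties broken by lexicographic (label_i, label_j) pair.
ranked_edges <- function(weights) {
  n <- nrow(weights)
  ut <- which(upper.tri(weights) & weights > 0, arr.ind = TRUE)
  if (nrow(ut) == 0L)
    return(data.frame(i = integer(), j = integer(), weight = numeric()))
  labs <- rownames(weights)
  w <- weights[ut]
  ord <- order(w, labs[ut[, 1]], labs[ut[, 2]], method = "radix")
  data.frame(i = ut[ord, 1], j = ut[ord, 2], weight = w[ord])
}
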