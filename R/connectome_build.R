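#' Normalize streamline counts by target-mask voxel counts
#'
#' Converts raw streamline counts to connection weights by dividing each
#' count by the voxel count of the target region mask, accounting for
#' between-group differences in regional gray matter volume. Because the
#' count matrix is symmetric while the target-mask ratio is
#' direction-dependent, the two directed ratios are averaged:
#' `w_ij = mean(c_ij / v_j, c_ij / v_i)`, which preserves symmetry while
#' honoring the per-target normalization.
#'
#' @param m a [streamline_matrix()].
#' @return A [weighted_network()] with provenance `"normalize_voxels"`.
#' @export
normalize_streamlines <- function(m) {
  stopifnot(inherits(m, "streamline_matrix"))
  v <- m$atlas$voxel_count
  if (any(v < 1))
    stop("voxel count < 1 for region(s): ",
         paste(m$atlas$label[v < 1], collapse = ", "))
  inv <- 1 / v
  w <- m$counts * (outer(inv, rep(1, length(v))) +
                     outer(rep(1, length(v)), inv)) / 2
  weighted_network(w, m$atlas, provenance = "normalize_voxels",
                   subject_id = m$subject_id, group = m$group)
}

#' Proportionally threshold a cohort of networks to a target density
#'
#' Two steps, applied to the whole cohort: (1) every weight is rescaled by
#' the single maximum edge weight pooled across all networks, so weights
#' are expressed relative to the cohort-wide maximum (the rescale affects
#' stored weights, not edge selection, since per-network rank removal is
#' scale-invariant); (2) within each network, the weakest nonzero edges are
#' removed, beginning with the weakest links, until the density is at most
#' `target_density`. Networks already at or below the target keep all their
#' edges. Ties are broken deterministically by lexicographic node-label
#' pair.
#'
#' @param networks a list of [weighted_network()]s (a single network is
#'   accepted and wrapped).
#' @param target_density fraction of possible edges to retain, in `(0, 1]`.
#' @return A list of thresholded [weighted_network()]s (or a single network
#'   if a single network was supplied).
#' @export
proportional_threshold <- function(networks, target_density = 0.5) {
  single <- inherits(networks, "weighted_network")
  if (single) networks <- list(networks)
  if (length(networks) == 0L) stop("empty cohort")
  if (target_density <= 0 || target_density > 1)
    stop("target_density must be in (0, 1]")
  wmax <- max(vapply(networks, function(x) max(x$weights), numeric(1)))
  if (wmax == 0) stop("all networks have zero weights")
  out <- lapply(networks, function(net) {
    w <- net$weights / wmax
    n <- nrow(w)
    max_edges <- floor(target_density * n * (n - 1) / 2)
    edges <- ranked_edges(w)
    n_remove <- max(0L, nrow(edges) - max_edges)
    if (n_remove > 0L) {
      drop <- edges[seq_len(n_remove), ]
      w[cbind(drop$i, drop$j)] <- 0
      w[cbind(drop$j, drop$i)] <- 0
    }
    weighted_network(w, net$atlas,
                     provenance = c(net$provenance, "rescale_pooled_max",
                                    sprintf("proportional_threshold_%g",
                                            target_density)),
                     subject_id = net$subject_id, group = net$group)
  })
  if (single) out[[1]] else out
}

#' Prune the weakest edges of a network
#'
#' Removes the `floor(fraction * E)` weakest nonzero edges of a network
#' (`E` = nonzero edge count before pruning), correcting for residual,
#' potentially spurious connections. Ties broken by lexicographic
#' node-label pair.
#'
#' @param net a [weighted_network()].
#' @param fraction fraction of nonzero edges to remove, in `[0, 1)`.
#' @return The pruned [weighted_network()].
#' @export
prune_weak <- function(net, fraction = 0.10) {
  stopifnot(inherits(net, "weighted_network"))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  w <- net$weights
  edges <- ranked_edges(w)
  n_remove <- floor(fraction * nrow(edges))
  if (n_remove > 0L) {
    drop <- edges[seq_len(n_remove), ]
    w[cbind(drop$i, drop$j)] <- 0
    w[cbind(drop$j, drop$i)] <- 0
  }
  weighted_network(w, net$atlas,
                   provenance = c(net$provenance,
                                  sprintf("prune_weak_%g", fraction)),
                   subject_id = net$subject_id, group = net$group)
}

#' Edgewise average of a group of networks
#'
#' The group-level structural network: the arithmetic mean of the (already
#' thresholded) weight matrices of all subjects in one group.
#'
#' @param networks list of [weighted_network()]s sharing one atlas.
#' @param group optional group label for the result.
#' @return A [weighted_network()].
#' @export
group_average <- function(networks, group = NA_character_) {
  if (inherits(networks, "weighted_network")) networks <- list(networks)
  if (length(networks) == 0L) stop("empty group")
  labs <- networks[[1]]$atlas$label
  for (net in networks)
    if (!identical(net$atlas$label, labs))
      stop("all networks must share one atlas")
  w <- Reduce(`+`, lapply(networks, `[[`, "weights")) / length(networks)
  if (is.na(group)) {
    gs <- unique(vapply(networks, `[[`, "", "group"))
    if (length(gs) == 1L) group <- gs
  }
  weighted_network(w, networks[[1]]$atlas,
                   provenance = c(networks[[1]]$provenance,
                                  sprintf("group_average_n%d",
                                          length(networks))),
                   group = group)
}

#' Build thresholded networks from a cohort of streamline matrices
#'
#' Runs the full network construction scheme over a cohort: voxel-count
#' normalization per subject, cohort-referenced proportional thresholding
#' to the target density, then per-network pruning of the weakest edges.
#'
#' @param subjects list of [streamline_matrix()].
#' @param target_density proportional-threshold density (default 0.5).
#' @param prune_fraction weakest-edge prune fraction (default 0.10).
#' @return A list of [weighted_network()]s, one per subject.
#' @export
build_networks <- function(subjects, target_density = 0.5,
                           prune_fraction = 0.10) {
  nets <- lapply(subjects, normalize_streamlines)
  nets <- proportional_threshold(nets, target_density)
  lapply(nets, prune_weak, fraction = prune_fraction)
}
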