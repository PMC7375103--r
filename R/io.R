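#' Write an adjacency matrix as TSV
#'
#' Header row of region labels; cells are the matrix entries. The format is
#' the on-disk interchange for both raw streamline counts and processed
#' weights.
#'
#' @param mat square matrix with region labels as dimnames.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_adjacency_tsv <- function(mat, path) {
  mat <- if (inherits(mat, "weighted_network")) mat$weights else as.matrix(mat)
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an adjacency matrix from TSV
#'
#' @param path file written by [write_adjacency_tsv()].
#' @return A square numeric matrix with labels as dimnames.
#' @export
read_adjacency_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m))
    stop("adjacency file is not square: ", path)
  rownames(m) <- colnames(m)
  m
}

#' Export a partitioned network to GraphML
#'
#' Writes a standard GraphML file with edge weights and node attributes:
#' region label, hemisphere, community module, nodal degree and strength,
#' and (when a hub table is supplied) hub basis flags and hub class.
#'
#' @param net a [weighted_network()].
#' @param path destination file.
#' @param partition optional [louvain_partition()] result (or named module
#'   vector).
#' @param hubs optional hub table from [identify_hubs()].
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path, partition = NULL, hubs = NULL) {
  g <- as_igraph(net)
  igraph::V(g)$label <- net$atlas$label
  igraph::V(g)$hemisphere <- net$atlas$hemisphere
  if (!is.null(partition)) {
    assign <- if (inherits(partition, "louvain_partition"))
      partition$assignment else partition
    igraph::V(g)$module <- as.integer(assign[net$atlas$label])
  }
  igraph::V(g)$degree <- nodal_degree(net)
  igraph::V(g)$strength <- nodal_strength(net)
  if (!is.null(hubs)) {
    igraph::V(g)$hub_degree <- net$atlas$label %in%
      hubs$node[hubs$basis == "degree"]
    igraph::V(g)$hub_strength <- net$atlas$label %in%
      hubs$node[hubs$basis == "strength"]
    klass <- rep(NA_character_, n_regions(net$atlas))
    for (i in seq_len(nrow(hubs)))
      klass[match(hubs$node[i], net$atlas$label)] <- hubs$klass[i]
    igraph::V(g)$hub_class <- klass
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
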