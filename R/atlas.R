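#' Construct a region atlas
#'
#' An atlas defines the node identity space of every network in a study: an
#' ordered set of uniquely labeled brain regions, their hemisphere, and the
#' number of voxels in each region mask. Voxel counts are used to normalize
#' raw streamline counts (see [normalize_streamlines()]); region masks are
#' registered once per study, so voxel counts are shared across subjects.
#'
#' @param labels character vector of unique region labels, in atlas order.
#' @param hemisphere per-region hemisphere tag: `"L"`, `"R"` or `"M"`
#'   (midline).
#' @param voxel_counts per-region positive integer voxel counts.
#' @return A `data.frame` of class `atlas_spec` with columns `label`,
#'   `hemisphere` and `voxel_count`.
#' @seealso [default_atlas()], [read_atlas()]
#' @export
atlas_spec <- function(labels, hemisphere, voxel_counts) {
  labels <- as.character(labels)
  if (anyDuplicated(labels) > 0L)
    stop("atlas region labels must be unique")
  if (length(hemisphere) != length(labels) ||
      length(voxel_counts) != length(labels))
    stop("labels, hemisphere and voxel_counts must have equal length")
  if (!all(hemisphere %in% c("L", "R", "M")))
    stop("hemisphere tags must be 'L', 'R' or 'M'")
  voxel_counts <- as.integer(voxel_counts)
  if (anyNA(voxel_counts) || any(voxel_counts < 1L))
    stop("all voxel counts must be integers >= 1")
  out <- data.frame(label = labels, hemisphere = hemisphere,
                    voxel_count = voxel_counts)
  class(out) <- c("atlas_spec", "data.frame")
  out
}

#' Number of regions in an atlas
#' @param atlas an [atlas_spec()].
#' @return integer region count.
#' @export
n_regions <- function(atlas) nrow(atlas)

#' The packaged 116-region macrolabel atlas
#'
#' Returns the default whole-brain parcellation used throughout the package:
#' 116 anatomical regions (45 bilateral cortical/subcortical pairs, 9
#' bilateral cerebellar pairs, and 8 midline vermis segments) following the
#' standard macrolabel naming. The voxel counts shipped with the atlas are
#' synthetic (log-normal around 500 voxels, frozen once), since region-mask
#' sizes are study-specific; replace them via [atlas_spec()] or
#' [read_atlas()] when real masks are available.
#'
#' @return An `atlas_spec` with 116 regions.
#' @export
default_atlas <- function() {
  path <- system.file("extdata", "atlas_macrolabel116_synthetic.tsv",
                      package = "connectoscope", mustWork = TRUE)
  read_atlas(path)
}

#' Read an atlas from a TSV file
#'
#' Expects a tab-separated file with a header row and columns `label`,
#' `hemisphere`, `voxel_count`.
#'
#' @param path file path.
#' @return An `atlas_spec`.
#' @export
read_atlas <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "hemisphere", "voxel_count")
  if (!all(need %in% names(tab)))
    stop("atlas file must have columns: ", paste(need, collapse = ", "))
  atlas_spec(tab$label, tab$hemisphere, tab$voxel_count)
}

#' Write an atlas to a TSV file
#' @param atlas an [atlas_spec()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(as.data.frame(atlas), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Resolve region labels to atlas indices, failing loudly on unknown names.
region_index <- function(atlas, regions) {
  idx <- match(regions, atlas$label)
  if (anyNA(idx))
    stop("unknown region(s): ",
         paste(regions[is.na(idx)], collapse = ", "))
  idx
}
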