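#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end connectome analysis
#' in one serializable object: cohort source, thresholding scheme, metric
#' normalization, community-detection iterations, and inference settings.
#'
#' @param cohort a [cohort_config()] to simulate, or `NULL` when reading
#'   from `input_dir`.
#' @param input_dir directory written by [write_cohort()] (ignored when
#'   `cohort` is given).
#' @param density_target proportional-threshold density (default 0.5).
#' @param prune_fraction weakest-edge prune fraction (default 0.10).
#' @param normalization metric normalization mode, `"total"` or `"none"`.
#' @param louvain_iterations Louvain iterations for consensus (default 100).
#' @param n_perm permutation-test iterations (default 10000).
#' @param alpha nodal significance level (default 0.016 = 0.05/3).
#' @param control_group name of the reference group (defaults to the first
#'   group of the cohort).
#' @param seed master RNG seed for the whole run.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), input_dir = NULL,
                            density_target = 0.5, prune_fraction = 0.10,
                            normalization = c("total", "none"),
                            louvain_iterations = 100, n_perm = 10000,
                            alpha = 0.016, control_group = NULL,
                            seed = 1L, out_dir = NULL) {
  normalization <- match.arg(normalization)
  if (is.null(cohort) && is.null(input_dir))
    stop("provide a cohort config or an input directory")
  if (density_target <= 0 || density_target > 1)
    stop("density_target must be in (0, 1]")
  if (prune_fraction < 0 || prune_fraction >= 1)
    stop("prune_fraction must be in [0, 1)")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  structure(list(cohort = cohort, input_dir = input_dir,
                 density_target = density_target,
                 prune_fraction = prune_fraction,
                 normalization = normalization,
                 louvain_iterations = louvain_iterations,
                 n_perm = n_perm, alpha = alpha,
                 control_group = control_group, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full connectome analysis pipeline
#'
#' Executes, in order: (1) cohort acquisition (simulation or disk read);
#' (2) network construction (voxel normalization, cohort-referenced
#' proportional thresholding, weak-edge pruning); (3) per-subject global
#' and nodal graph metrics; (4) group-averaged networks with consensus
#' Louvain partitions, hub identification, module-migration and hub
#' comparison of each patient group against controls; (5) group inference:
#' split-plot ANOVA on the global metrics, nodewise permutation tests on
#' degree/strength/betweenness, Spearman correlations of clinical
#' covariates with significantly altered nodal metrics, and demographic
#' comparisons. A manifest records every parameter, seed and per-group
#' final density; re-running an identical config reproduces all outputs.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `connectome_report` with elements `networks`,
#'   `group_networks`, `partitions`, `hubs`, `hub_comparisons`,
#'   `module_migrations`, `global_metrics`, `anova`, `nodal_tests`,
#'   `significant_nodes`, `clinical_correlations`, `demographics`,
#'   `manifest`. Written to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)

  # stage 1: cohort
  cohort <- if (!is.null(config$cohort))
    generate_cohort(config$cohort) else read_cohort(config$input_dir)
  groups <- unique(vapply(cohort$subjects, `[[`, "", "group"))
  control <- config$control_group %||% groups[1]
  if (!control %in% groups)
    stop("stage cohort: control group '", control, "' not present")

  # stage 2: networks
  nets <- build_networks(cohort$subjects,
                         target_density = config$density_target,
                         prune_fraction = config$prune_fraction)

  # stage 3: per-subject metrics
  subj_ids <- vapply(cohort$subjects, `[[`, "", "subject_id")
  subj_groups <- vapply(cohort$subjects, `[[`, "", "group")
  gm <- do.call(rbind, lapply(seq_along(nets), function(i)
    cbind(subject = subj_ids[i], group = subj_groups[i],
          global_metrics(nets[[i]], config$normalization))))
  nodal <- lapply(c("degree", "strength", "betweenness"), function(met) {
    fn <- switch(met, degree = nodal_degree, strength = nodal_strength,
                 betweenness = betweenness_centrality)
    m <- t(vapply(nets, fn, numeric(n_regions(cohort$atlas))))
    rownames(m) <- subj_ids
    m
  })
  names(nodal) <- c("degree", "strength", "betweenness")

  # stage 4: group networks, communities, hubs
  group_nets <- lapply(groups, function(g)
    group_average(nets[subj_groups == g], group = g))
  names(group_nets) <- groups
  partitions <- lapply(group_nets, louvain_partition,
                       n_iterations = config$louvain_iterations,
                       seed = config$seed)
  hubs <- lapply(groups, function(g)
    identify_hubs(group_nets[[g]], partitions[[g]]))
  names(hubs) <- groups
  patient_groups <- setdiff(groups, control)
  hub_comparisons <- lapply(patient_groups, function(g)
    compare_hubs(hubs[[control]], hubs[[g]]))
  names(hub_comparisons) <- patient_groups
  module_migrations <- lapply(patient_groups, function(g)
    module_migration(partitions[[control]], partitions[[g]]))
  names(module_migrations) <- patient_groups

  # stage 5: inference
  long <- data.frame(
    subject = rep(gm$subject, 3), group = rep(gm$group, 3),
    metric = rep(c("char_path_length", "global_efficiency",
                   "clustering_coefficient"), each = nrow(gm)),
    value = c(gm$char_path_length, gm$global_efficiency,
              gm$clustering_coefficient))
  anova_res <- anova_global(long)
  nodal_tests <- list()
  for (g in patient_groups) {
    per_metric <- lapply(names(nodal), function(met)
      cbind(group = g, metric = met,
            permutation_test_matrix(
              nodal[[met]][subj_groups == g, , drop = FALSE],
              nodal[[met]][subj_groups == control, , drop = FALSE],
              n_perm = config$n_perm, alpha = config$alpha,
              seed = config$seed)))
    nodal_tests[[g]] <- do.call(rbind, per_metric)
  }
  nodal_tests <- do.call(rbind, nodal_tests)
  rownames(nodal_tests) <- NULL
  significant <- significance_filter(nodal_tests, config$alpha)

  clin_cor <- list()
  clin <- cohort$clinical
  clin_vars <- intersect(c("onset_age", "duration", "bfm_movement",
                           "bfm_disability"), names(clin))
  for (i in seq_len(nrow(significant))) {
    g <- significant$group[i]; met <- significant$metric[i]
    node <- significant$node[i]
    vals <- nodal[[met]][subj_groups == g, node]
    sub_clin <- clin[clin$group == g, , drop = FALSE]
    for (v in clin_vars) {
      if (all(is.na(sub_clin[[v]]))) next
      clin_cor[[length(clin_cor) + 1L]] <-
        cbind(group = g, metric = met,
              spearman_correlation(sub_clin[[v]], vals,
                                   variable = v, node = node))
    }
  }
  clin_cor <- if (length(clin_cor)) do.call(rbind, clin_cor) else NULL
  demographics <- lapply(patient_groups, function(g)
    demographics_compare(clin[clin$group == control, , drop = FALSE],
                         clin[clin$group == g, , drop = FALSE]))
  names(demographics) <- patient_groups

  manifest <- list(
    stages = c("cohort", "build", "metrics", "community_hubs",
               "inference"),
    parameters = list(density_target = config$density_target,
                      prune_fraction = config$prune_fraction,
                      normalization = config$normalization,
                      louvain_iterations = config$louvain_iterations,
                      n_perm = config$n_perm, alpha = config$alpha,
                      seed = config$seed),
    groups = as.list(table(subj_groups)),
    control_group = control,
    group_densities = lapply(group_nets, network_density),
    modularity_q = lapply(partitions, `[[`, "q"))

  report <- structure(
    list(cohort = cohort, networks = nets, group_networks = group_nets,
         partitions = partitions, hubs = hubs,
         hub_comparisons = hub_comparisons,
         module_migrations = module_migrations,
         global_metrics = gm, nodal_metrics = nodal, anova = anova_res,
         nodal_tests = nodal_tests, significant_nodes = significant,
         clinical_correlations = clin_cor, demographics = demographics,
         manifest = manifest),
    class = "connectome_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.connectome_report <- function(x, ...) {
  cat("<connectome_report>\n")
  cat("  groups:",
      paste(names(x$manifest$groups), unlist(x$manifest$groups),
            sep = "=", collapse = ", "), "\n")
  cat("  group densities:",
      paste(names(x$group_networks),
            sprintf("%.3f", unlist(x$manifest$group_densities)),
            sep = "=", collapse = ", "), "\n")
  cat("  modules:",
      paste(names(x$partitions),
            vapply(x$partitions, `[[`, 0L, "n_modules"),
            sep = "=", collapse = ", "), "\n")
  cat("  significant nodal differences:", nrow(x$significant_nodes), "\n")
  invisible(x)
}

# Serialize the report bundle: TSV tables, partition/manifest JSON, GraphML.
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(report$group_networks)) {
    write_adjacency_tsv(report$group_networks[[g]],
                        file.path(dir, paste0("group_", g, ".tsv")))
    p <- report$partitions[[g]]
    jsonlite::write_json(
      list(assignment = as.list(p$assignment), q = p$q,
           n_modules = p$n_modules, iteration_qs = p$iteration_qs,
           method = p$method, seed = p$seed),
      file.path(dir, paste0("partition_", g, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(report$hubs[[g]],
                       file.path(dir, paste0("hubs_", g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    export_graphml(report$group_networks[[g]],
                   file.path(dir, paste0("group_", g, ".graphml")),
                   partition = p, hubs = report$hubs[[g]])
  }
  utils::write.table(report$global_metrics,
                     file.path(dir, "global_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$nodal_tests,
                     file.path(dir, "nodal_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$clinical_correlations))
    utils::write.table(report$clinical_correlations,
                       file.path(dir, "clinical_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
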