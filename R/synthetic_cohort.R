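#' Configuration for a synthetic connectome cohort
#'
#' Describes a multi-subject cohort of streamline-count matrices with planted
#' community structure, hub architecture, group-level nodal effects, and
#' clinical covariates rank-correlated with nodal metrics. The defaults
#' emulate a three-group task-specific focal dystonia study design: 16
#' healthy controls and two patient groups of 17 (laryngeal dystonia, LD)
#' and 15 (writer's cramp, WC) subjects over a 116-region atlas organized
#' into 5 communities, with subcortical hubs (bilateral putamen, thalamus,
#' hippocampus, precuneus and right caudate).
#'
#' Edge counts follow a negative-binomial distribution (overdispersed, as
#' empirical streamline counts are) whose mean scales with the voxel counts
#' of both endpoint regions, so that downstream voxel normalization is
#' non-trivial. Edges exist on a cohort-shared anatomical backbone drawn
#' once per cohort (white-matter anatomy is common across subjects), denser
#' within planted modules than between them.
#'
#' @param groups named integer vector: subjects per group. The first group
#'   is treated as the control group.
#' @param n_modules number of planted communities.
#' @param within_weight_scale,between_weight_scale mean streamline count
#'   scale for edges inside vs. across planted modules; must satisfy
#'   `within > between >= 0`.
#' @param within_density,between_density backbone edge probabilities inside
#'   vs. across modules. Defaults give a raw network density near 30%,
#'   matching typical mammalian connectome density estimates.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param hub_nodes named numeric vector: region label -> strength
#'   multiplier applied to all edges incident to that region.
#' @param group_effects list of `list(group=, region=, multiplier=)` (or
#'   `shift=` for an additive change) applied to the designated group's
#'   matrices; creates ground truth for nodal permutation tests.
#' @param clinical_correlations list of
#'   `list(variable=, region=, group=, rho=)`: target Spearman correlation
#'   between a clinical variable and the subject-level nodal strength of a
#'   region within one group.
#' @param seed RNG seed governing every random draw in the generator.
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(groups = c(controls = 16L, LD = 17L, WC = 15L),
                          n_modules = 5L,
                          within_weight_scale = 30,
                          between_weight_scale = 10,
                          within_density = 0.75,
                          between_density = 0.22,
                          dispersion = 2,
                          hub_nodes = c(
                            Putamen_L = 1.8, Putamen_R = 1.8,
                            Thalamus_L = 1.8, Thalamus_R = 1.8,
                            Hippocampus_L = 1.8, Hippocampus_R = 1.8,
                            Precuneus_L = 1.8, Precuneus_R = 1.8,
                            Caudate_R = 1.8),
                          group_effects = list(
                            list(group = "LD", region = "Supp_Motor_Area_R",
                                 multiplier = 1.3),
                            list(group = "WC", region = "Insula_L",
                                 multiplier = 0.75),
                            list(group = "WC", region = "Cingulum_Ant_R",
                                 multiplier = 0.75)),
                          clinical_correlations = list(
                            list(variable = "duration", region = "Caudate_L",
                                 group = "LD", rho = -0.50),
                            list(variable = "onset_age", region = "Insula_L",
                                 group = "LD", rho = 0.51),
                            list(variable = "bfm_movement",
                                 region = "Pallidum_R", group = "WC",
                                 rho = 0.63)),
                          seed = 1L) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named vector")
  # default effect/correlation specs adapt to whichever groups are present
  keep_known <- function(specs) Filter(function(s)
    s$group %in% names(groups), specs)
  if (missing(group_effects)) group_effects <- keep_known(group_effects)
  if (missing(clinical_correlations))
    clinical_correlations <- keep_known(clinical_correlations)
  if (any(groups < 2)) stop("every group needs at least 2 subjects")
  if (n_modules < 1) stop("n_modules must be >= 1")
  if (!(within_weight_scale > between_weight_scale))
    stop("within_weight_scale must exceed between_weight_scale")
  if (between_weight_scale < 0) stop("between_weight_scale must be >= 0")
  for (cc in clinical_correlations)
    if (abs(cc$rho) > 1) stop("target rank correlations must lie in [-1, 1]")
  structure(list(groups = groups, n_modules = as.integer(n_modules),
                 within_weight_scale = within_weight_scale,
                 between_weight_scale = between_weight_scale,
                 within_density = within_density,
                 between_density = between_density,
                 dispersion = dispersion, hub_nodes = hub_nodes,
                 group_effects = group_effects,
                 clinical_correlations = clinical_correlations,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort of streamline-count matrices
#'
#' Draws a cohort under a [cohort_config()]: one shared anatomical backbone,
#' per-subject negative-binomial streamline counts, planted group effects,
#' and a clinical covariate table. Identical `(config, atlas)` always
#' reproduces identical output.
#'
#' @param config a [cohort_config()].
#' @param atlas an [atlas_spec()]; defaults to the packaged 116-region atlas.
#' @return A list of class `synthetic_cohort` with elements `subjects` (list
#'   of [streamline_matrix()]), `clinical` (data.frame), `atlas`, and
#'   `planted` (ground truth: `modules` as a named module-id vector,
#'   `hub_nodes`, `nodal_strength` matrix, and the `config`).
#' @export
generate_cohort <- function(config, atlas = default_atlas()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- n_regions(atlas)
  if (config$n_modules > n)
    stop("n_modules (", config$n_modules, ") exceeds the ",
         n, " atlas regions")
  region_index(atlas, names(config$hub_nodes))
  for (ge in config$group_effects) region_index(atlas, ge$region)
  for (cc in config$clinical_correlations) region_index(atlas, cc$region)
  bad <- setdiff(c(vapply(config$group_effects, `[[`, "", "group"),
                   vapply(config$clinical_correlations, `[[`, "", "group")),
                 names(config$groups))
  if (length(bad))
    stop("unknown group(s) in effect/correlation spec: ",
         paste(bad, collapse = ", "))

  set.seed(config$seed)
  # planted community labels: contiguous near-equal blocks in atlas order
  sizes <- diff(floor(seq(0, n, length.out = config$n_modules + 1)))
  modules <- rep(seq_len(config$n_modules), times = sizes)
  names(modules) <- atlas$label

  same <- outer(modules, modules, "==")
  ut <- upper.tri(same)
  hub_mult <- rep(1, n)
  hub_mult[region_index(atlas, names(config$hub_nodes))] <- config$hub_nodes
  hf <- outer(hub_mult, hub_mult)
  # shared backbone: anatomy is subject-invariant; hubs are both better
  # connected (degree) and more strongly connected (strength)
  p_edge <- ifelse(same[ut], config$within_density, config$between_density)
  p_edge <- pmin(1, p_edge * sqrt(hf[ut]))
  backbone <- stats::rbinom(length(p_edge), 1L, p_edge)

  # expected counts scale with endpoint voxel counts and hub multipliers
  v <- atlas$voxel_count
  vf <- outer(v, v) / mean(v)^2
  scale_mat <- ifelse(same, config$within_weight_scale,
                      config$between_weight_scale)
  mu <- (scale_mat * vf * hf)[ut] * backbone

  group_of <- rep(names(config$groups), times = config$groups)
  subjects <- vector("list", length(group_of))
  for (s in seq_along(group_of)) {
    cts <- stats::rnbinom(length(mu), mu = mu, size = config$dispersion)
    cts[mu == 0] <- 0L
    m <- matrix(0, n, n)
    m[ut] <- cts
    m <- m + t(m)
    subjects[[s]] <- streamline_matrix(
      m, atlas,
      subject_id = sprintf("%s_%02d", group_of[s],
                           sum(group_of[seq_len(s)] == group_of[s])),
      group = group_of[s])
  }

  for (ge in config$group_effects)
    subjects <- plant_group_effect(subjects, region = ge$region,
                                   group = ge$group,
                                   multiplier = ge$multiplier,
                                   shift = ge$shift)

  # ground-truth nodal metric: voxel-normalized strength per subject
  strength <- t(vapply(subjects, function(s)
    nodal_strength(normalize_streamlines(s)), numeric(n)))
  rownames(strength) <- vapply(subjects, `[[`, "", "subject_id")

  clinical <- generate_clinical(config, group_of, strength)
  clinical$subject_id <- rownames(strength)
  clinical <- clinical[, c("subject_id",
                           setdiff(names(clinical), "subject_id"))]

  structure(list(subjects = subjects, clinical = clinical, atlas = atlas,
                 planted = list(modules = modules,
                                hub_nodes = config$hub_nodes,
                                nodal_strength = strength,
                                config = config)),
            class = "synthetic_cohort")
}

#' Plant a nodal group effect into streamline matrices
#'
#' Applies a multiplicative (or additive) change to all streamline counts
#' incident to one region, in the matrices of one group only, preserving
#' symmetry, integrality and the zero diagonal. This is the ground truth
#' that nodal permutation tests are expected to recover.
#'
#' @param subjects list of [streamline_matrix()].
#' @param region region label.
#' @param group group label whose matrices are modified.
#' @param multiplier multiplicative factor for the region's row/column
#'   (rounded back to integers); `1` leaves matrices unchanged.
#' @param shift additive change per incident edge (applied to nonzero
#'   entries); may be negative but must not produce negative counts.
#' @return The modified list of subjects.
#' @export
plant_group_effect <- function(subjects, region, group, multiplier = NULL,
                               shift = NULL) {
  if (is.null(multiplier) && is.null(shift))
    stop("specify multiplier or shift")
  for (s in seq_along(subjects)) {
    subj <- subjects[[s]]
    if (!identical(subj$group, group)) next
    r <- region_index(subj$atlas, region)
    row <- subj$counts[r, ]
    if (!is.null(multiplier)) {
      row <- round(row * multiplier)
    } else {
      row <- ifelse(row > 0, row + shift, row)
    }
    if (any(row < 0))
      stop("group effect would produce negative counts at ", region)
    subj$counts[r, ] <- row
    subj$counts[, r] <- row
    subj$counts[r, r] <- 0
    subjects[[s]] <- subj
  }
  subjects
}

# marginal parameters (mean, sd) of clinical covariates per group role,
# patterned on a typical task-specific focal dystonia cohort
clinical_params <- function(group, control) {
  if (group == control)
    return(list(age = c(55.3, 11.3), sex_f = 10 / 16))
  params <- list(
    LD = list(onset_age = c(37.4, 12.6), duration = c(19.2, 9.7),
              bfm_movement = c(3.6, 2.5), bfm_disability = c(2.1, 0.9),
              sex_f = 10 / 17),
    WC = list(onset_age = c(37.7, 10.3), duration = c(16.1, 10.7),
              bfm_movement = c(4.3, 2.6), bfm_disability = c(1.7, 0.8),
              sex_f = 9 / 15))
  if (group %in% names(params)) params[[group]]
  else list(onset_age = c(37.5, 11.5), duration = c(18, 10),
            bfm_movement = c(4, 2.5), bfm_disability = c(2, 0.9),
            sex_f = 0.6)
}

# quantile of a normal truncated below at 0 (keeps copula ranks intact
# while guaranteeing non-negative scores/durations)
qtnorm0 <- function(u, mean, sd) {
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + u * (1 - p0), mean, sd)
}

#' Generate clinical covariates for a cohort
#'
#' Draws group, age, sex, onset age, disease duration and severity scores
#' (movement and disability scales) per subject, then enforces any requested
#' Spearman correlations between a clinical variable and a region's planted
#' nodal metric through a Gaussian copula: the target rank correlation
#' `rho_s` is converted to the corresponding normal-copula correlation
#' `2 sin(pi * rho_s / 6)` and the variable's marginal (a zero-truncated
#' normal) is applied by quantile transform, so ranks are controlled
#' directly. Patient age is the sum of onset age and duration. Uses the
#' current RNG stream; called inside [generate_cohort()] after matrix
#' generation.
#'
#' @param config a [cohort_config()].
#' @param subject_groups character vector of per-subject group labels.
#' @param nodal_metric numeric matrix (subjects x regions) of the planted
#'   ground-truth nodal metric the correlations refer to.
#' @return A data.frame with one row per subject.
#' @export
generate_clinical <- function(config, subject_groups, nodal_metric) {
  control <- names(config$groups)[1]
  ns <- length(subject_groups)
  clin <- data.frame(group = subject_groups,
                     age = NA_real_, sex = NA_character_,
                     onset_age = NA_real_, duration = NA_real_,
                     bfm_movement = NA_real_, bfm_disability = NA_real_)
  for (g in unique(subject_groups)) {
    idx <- which(subject_groups == g)
    par <- clinical_params(g, control)
    clin$sex[idx] <- ifelse(stats::runif(length(idx)) < par$sex_f, "F", "M")
    if (g == control) {
      clin$age[idx] <- qtnorm0(stats::runif(length(idx)),
                               par$age[1], par$age[2])
    } else {
      for (v in c("onset_age", "duration", "bfm_movement",
                  "bfm_disability"))
        clin[[v]][idx] <- qtnorm0(stats::runif(length(idx)),
                                  par[[v]][1], par[[v]][2])
    }
  }
  for (cc in config$clinical_correlations) {
    if (abs(cc$rho) > 1) stop("target rank correlation outside [-1, 1]")
    idx <- which(subject_groups == cc$group)
    par <- clinical_params(cc$group, control)
    if (is.null(par[[cc$variable]]))
      stop("variable ", cc$variable, " is not generated for group ",
           cc$group)
    m <- nodal_metric[idx, cc$region]
    z_m <- stats::qnorm((rank(m, ties.method = "average") - 0.5) /
                          length(m))
    r_pearson <- 2 * sin(pi * cc$rho / 6)
    z_c <- r_pearson * z_m +
      sqrt(max(0, 1 - r_pearson^2)) * stats::rnorm(length(m))
    clin[[cc$variable]][idx] <- qtnorm0(stats::pnorm(z_c),
                                        par[[cc$variable]][1],
                                        par[[cc$variable]][2])
  }
  patients <- subject_groups != control
  clin$age[patients] <- clin$onset_age[patients] + clin$duration[patients]
  clin
}

#' Write a cohort to disk
#'
#' Writes per-subject adjacency TSVs (header row of region labels, integer
#' cells), the atlas metadata TSV, the clinical table TSV, and a generation
#' manifest JSON recording the full configuration and seed. Output is
#' byte-identical for identical cohorts.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  for (s in cohort$subjects)
    write_adjacency_tsv(s$counts, file.path(dir,
                                            paste0(s$subject_id, ".tsv")))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    config = unclass(cohort$planted$config),
    planted_modules = as.list(cohort$planted$modules),
    subjects = vapply(cohort$subjects, `[[`, "", "subject_id"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return A list with `subjects`, `clinical` and `atlas` as in
#'   [generate_cohort()] (no planted ground truth).
#' @export
read_cohort <- function(dir) {
  atlas <- read_atlas(file.path(dir, "atlas.tsv"))
  clinical <- utils::read.delim(file.path(dir, "clinical.tsv"),
                                stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(clinical)), function(i) {
    id <- clinical$subject_id[i]
    streamline_matrix(read_adjacency_tsv(file.path(dir,
                                                   paste0(id, ".tsv"))),
                      atlas, subject_id = id, group = clinical$group[i])
  })
  list(subjects = subjects, clinical = clinical, atlas = atlas)
}
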