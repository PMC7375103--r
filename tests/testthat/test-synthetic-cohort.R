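small_config <- function(...) {
  cohort_config(groups = c(controls = 4L, LD = 4L), seed = 42L, ...)
}

test_that("identical config yields bit-identical cohorts on disk", {
  c1 <- generate_cohort(small_config())
  c2 <- generate_cohort(small_config())
  expect_identical(lapply(c1$subjects, `[[`, "counts"),
                   lapply(c2$subjects, `[[`, "counts"))
  expect_identical(c1$clinical, c2$clinical)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  files <- list.files(d1)
  expect_identical(unname(tools::md5sum(file.path(d1, files))),
                   unname(tools::md5sum(file.path(d2, files))))
})

test_that("generated matrices are valid streamline matrices with planted
           module contrast", {
  co <- generate_cohort(small_config())
  modules <- co$planted$modules
  same <- outer(modules, modules, "==")
  for (s in co$subjects) {
    m <- s$counts
    expect_true(all(m == t(m)))
    expect_true(all(m >= 0) && all(m == round(m)))
    expect_true(all(diag(m) == 0))
    expect_equal(dim(m), c(116, 116))
  }
  pooled <- Reduce(`+`, lapply(co$subjects, `[[`, "counts"))
  ut <- upper.tri(pooled)
  expect_gt(mean(pooled[ut][same[ut]]), mean(pooled[ut][!same[ut]]))
})

test_that("zero between-module scale yields block-diagonal matrices", {
  co <- generate_cohort(small_config(between_weight_scale = 0))
  modules <- co$planted$modules
  cross <- !outer(modules, modules, "==")
  for (s in co$subjects) expect_true(all(s$counts[cross] == 0))
})

test_that("configuration errors are caught", {
  expect_error(generate_cohort(small_config(
    hub_nodes = c(Nonexistent_L = 2))), "unknown region")
  expect_error(generate_cohort(small_config(n_modules = 200L)),
               "exceeds")
  expect_error(cohort_config(groups = c(controls = 1L)), "at least 2")
  expect_error(cohort_config(within_weight_scale = 5,
                             between_weight_scale = 10), "exceed")
  expect_error(generate_cohort(small_config(group_effects = list(
    list(group = "nope", region = "Insula_L", multiplier = 2)))),
    "unknown group")
})

test_that("plant_group_effect scales one group's nodal strength and
           preserves matrix structure", {
  co <- generate_cohort(small_config(group_effects = list()))
  region <- "Putamen_L"
  # oracle: strengths recomputed directly from raw counts
  strength_at <- function(subjects, grp)
    vapply(Filter(function(s) s$group == grp, subjects),
           function(s) sum(s$counts[region, ]), 0)
  base_ld <- strength_at(co$subjects, "LD")
  base_hc <- strength_at(co$subjects, "controls")

  unchanged <- plant_group_effect(co$subjects, region, "LD",
                                  multiplier = 1.0)
  expect_identical(lapply(unchanged, `[[`, "counts"),
                   lapply(co$subjects, `[[`, "counts"))

  doubled <- plant_group_effect(co$subjects, region, "LD",
                                multiplier = 2.0)
  expect_equal(strength_at(doubled, "LD"), 2 * base_ld)
  expect_equal(strength_at(doubled, "controls"), base_hc)
  for (s in doubled) {
    expect_true(all(s$counts == t(s$counts)))
    expect_true(all(s$counts == round(s$counts)))
    expect_true(all(diag(s$counts) == 0))
  }
  expect_error(plant_group_effect(co$subjects, region, "LD",
                                  shift = -1e9), "negative")
})

test_that("consensus Louvain recovers the planted five communities and
           hubs on group-averaged networks across seeds", {
  seeds <- 1:20
  ari <- numeric(length(seeds))
  hubs_found <- logical(length(seeds))
  for (i in seq_along(seeds)) {
    cfg <- cohort_config(groups = c(controls = 8L), seed = seeds[i])
    co <- generate_cohort(cfg)
    nets <- build_networks(co$subjects)
    ga <- group_average(nets, group = "controls")
    part <- louvain_partition(ga, n_iterations = 50, seed = seeds[i])
    ari[i] <- mclust::adjustedRandIndex(part$assignment,
                                        co$planted$modules)
    hb <- identify_hubs(ga, part)
    hubs_found[i] <- all(names(co$planted$hub_nodes) %in% hb$node)
  }
  expect_gte(mean(ari >= 0.9), 0.9)
  expect_gte(mean(hubs_found), 0.9)
})

test_that("copula-generated clinical covariates honor target rank
           correlations", {
  # perfect monotone coupling: rank correlation exactly 1
  cfg <- cohort_config(groups = c(controls = 4L, LD = 16L),
                       clinical_correlations = list(
                         list(variable = "duration", region = "Insula_L",
                              group = "LD", rho = 1)),
                       seed = 5L)
  co <- generate_cohort(cfg)
  ld <- co$clinical$group == "LD"
  rho <- cor(co$clinical$duration[ld],
             co$planted$nodal_strength[ld, "Insula_L"],
             method = "spearman")
  expect_equal(rho, 1)

  # a strong negative target at n = 15 lands inside the simulation band
  realized <- vapply(1:30, function(s) {
    cfg <- cohort_config(groups = c(controls = 4L, WC = 15L),
                         clinical_correlations = list(
                           list(variable = "bfm_disability",
                                region = "Rectus_L", group = "WC",
                                rho = -0.76)),
                         seed = s)
    co <- generate_cohort(cfg)
    wc <- co$clinical$group == "WC"
    cor(co$clinical$bfm_disability[wc],
        co$planted$nodal_strength[wc, "Rectus_L"], method = "spearman")
  }, 0)
  expect_gte(mean(realized >= -0.95 & realized <= -0.45), 0.85)

  # target 0: realized rho behaves like the null distribution of
  # Spearman's rho (oracle: its null SD at n is 1/sqrt(n - 1))
  realized0 <- vapply(1:30, function(s) {
    cfg <- cohort_config(groups = c(controls = 4L, LD = 16L),
                         clinical_correlations = list(
                           list(variable = "duration",
                                region = "Insula_L", group = "LD",
                                rho = 0)),
                         seed = s + 100L)
    co <- generate_cohort(cfg)
    ld <- co$clinical$group == "LD"
    cor(co$clinical$duration[ld],
        co$planted$nodal_strength[ld, "Insula_L"], method = "spearman")
  }, 0)
  null_q95 <- qnorm(0.975) / sqrt(15)  # ~0.506
  expect_gte(mean(abs(realized0) <= null_q95), 0.85)
  expect_lt(abs(mean(realized0)), 0.2)

  expect_error(cohort_config(clinical_correlations = list(
    list(variable = "duration", region = "Insula_L", group = "LD",
         rho = 1.2))), "\\[-1, 1\\]")
})

test_that("clinical tables satisfy their structural invariants", {
  co <- generate_cohort(small_config())
  clin <- co$clinical
  patients <- clin$group == "LD"
  expect_true(all(clin$duration[patients] >= 0))
  expect_true(all(c(clin$bfm_movement[patients],
                    clin$bfm_disability[patients]) >= 0))
  expect_equal(clin$age[patients],
               clin$onset_age[patients] + clin$duration[patients])
  expect_true(all(clin$sex %in% c("F", "M")))
  expect_true(all(is.na(clin$onset_age[!patients])))
})
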