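#' Nonparametric permutation test for a group difference
#'
#' Tests a difference in group means by shuffling subject group labels. The
#' statistic is the standard difference score (SDS): the difference of
#' group means `mean(x) - mean(y)`. The two-sided p-value uses the add-one
#' estimator `p = (1 + #{|null| >= |observed|}) / (n_perm + 1)`, so `p` is
#' never 0 and is a valid p-value under exchangeability. With
#' `exact = TRUE` the null is the full enumeration of all label
#' assignments (feasible for small groups) and `p` is the exact proportion.
#'
#' @param x,y numeric per-subject metric values for the two groups (at
#'   least 2 each).
#' @param n_perm number of label shuffles (default 10000).
#' @param alpha significance level; 0.016 by default (0.05 Bonferroni
#'   corrected over the three nodal metrics).
#' @param seed optional RNG seed.
#' @param exact enumerate all `choose(n, nx)` assignments instead of
#'   sampling.
#' @return A list of class `permutation_result`: `sds`, `mean_x`, `mean_y`,
#'   `p`, `n_perm`, `alpha`, `significant`.
#' @export
permutation_test <- function(x, y, n_perm = 10000, alpha = 0.016,
                             seed = NULL, exact = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 subjects")
  res <- permutation_test_matrix(cbind(as.numeric(x)),
                                 cbind(as.numeric(y)),
                                 n_perm = n_perm, alpha = alpha,
                                 seed = seed, exact = exact)
  structure(list(sds = res$sds[1], mean_x = mean(x), mean_y = mean(y),
                 p = res$p[1], n_perm = res$n_perm, alpha = alpha,
                 significant = res$p[1] <= alpha),
            class = "permutation_result")
}

#' Permutation tests for many nodes at once
#'
#' Matrix version of [permutation_test()]: rows are subjects, columns are
#' nodes (or metrics). One common set of label permutations is applied to
#' every column, as is standard for nodewise network comparisons.
#'
#' @param a,b numeric matrices (subjects x nodes) for the two groups.
#' @inheritParams permutation_test
#' @return A data.frame with one row per column: `sds`, `p`,
#'   `significant`, plus attributes-free columns `mean_a`, `mean_b`;
#'   `n_perm` is attached as a column-constant field.
#' @export
permutation_test_matrix <- function(a, b, n_perm = 10000, alpha = 0.016,
                                    seed = NULL, exact = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("each group needs at least 2 subjects")
  if (ncol(a) != ncol(b)) stop("groups must have the same columns")
  if (!is.null(seed)) set.seed(seed)
  z <- rbind(a, b)
  na <- nrow(a); nb <- nrow(b); n <- na + nb
  obs <- colMeans(a) - colMeans(b)
  tot <- colSums(z)
  if (exact) {
    combos <- utils::combn(n, na)
    if (ncol(combos) > 2e5)
      stop("exact enumeration infeasible: ", ncol(combos), " assignments")
    null_sa <- apply(combos, 2, function(idx) colSums(z[idx, , drop = FALSE]))
    null_sa <- matrix(null_sa, nrow = ncol(z))
    null <- null_sa / na - (tot - null_sa) / nb  # cols = assignments
    exceed <- rowSums(abs(null) >= abs(obs) - 1e-12)
    p <- exceed / ncol(combos)
    n_eff <- ncol(combos)
  } else {
    exceed <- rep(0L, ncol(z))
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n, na)
      sa <- colSums(z[idx, , drop = FALSE])
      d <- sa / na - (tot - sa) / nb
      exceed <- exceed + (abs(d) >= abs(obs) - 1e-12)
    }
    p <- (1 + exceed) / (n_perm + 1)
    n_eff <- n_perm
  }
  data.frame(node = colnames(z) %||% seq_len(ncol(z)),
             mean_a = colMeans(a), mean_b = colMeans(b),
             sds = obs, p = p, n_perm = n_eff, alpha = alpha,
             significant = p <= alpha, row.names = NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Standard difference score
#'
#' The difference of patient and control group means of a nodal metric.
#'
#' @param mean_patients,mean_controls group means.
#' @return `mean_patients - mean_controls`.
#' @export
compute_sds <- function(mean_patients, mean_controls) {
  mean_patients - mean_controls
}

#' Split-plot ANOVA for global network metrics
#'
#' Two-way analysis of variance with subject group as the between-subject
#' factor and graph measure (characteristic path length, global efficiency,
#' clustering coefficient) as the within-subject factor. The group main
#' effect is tested against between-subject error with
#' `df = (k - 1, N - k)`; the group-by-measure interaction against
#' within-subject error with `df = ((k - 1)(m - 1), (N - k)(m - 1))`. When
#' the group effect or the interaction is significant at `alpha`, follow-up
#' post hoc univariate F-tests compare the groups separately per measure.
#'
#' @param data data.frame with columns `subject`, `group`, `metric`,
#'   `value`; every subject must have every metric exactly once.
#' @param alpha overall significance level for triggering post hoc tests
#'   (default 0.05).
#' @return A list of class `anova_global`: `effects` (data.frame `effect`,
#'   `df_num`, `df_den`, `f_value`, `p`) and `posthoc` (per-metric
#'   univariate F table, or NULL when not triggered).
#' @export
anova_global <- function(data, alpha = 0.05) {
  need <- c("subject", "group", "metric", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  counts <- table(data$subject, data$metric)
  if (any(counts != 1))
    stop("every subject must have every metric exactly once")
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$metric <- factor(data$metric)
  fit <- stats::aov(value ~ group * metric + Error(subject),
                    data = data)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    resid <- match("Residuals", trimws(rownames(tab)))
    data.frame(effect = term, df_num = tab$Df[i], df_den = tab$Df[resid],
               f_value = tab$`F value`[i], p = tab$`Pr(>F)`[i])
  }
  effects <- rbind(pick(between, "group"),
                   pick(within, "metric"),
                   pick(within, "group:metric"))
  rownames(effects) <- NULL
  posthoc <- NULL
  trigger <- effects$p[effects$effect %in% c("group", "group:metric")]
  if (any(trigger <= alpha)) {
    posthoc <- do.call(rbind, lapply(levels(data$metric), function(m) {
      sub <- data[data$metric == m, ]
      a <- stats::anova(stats::lm(value ~ group, data = sub))
      data.frame(metric = m, df_num = a$Df[1], df_den = a$Df[2],
                 f_value = a$`F value`[1], p = a$`Pr(>F)`[1])
    }))
    rownames(posthoc) <- NULL
  }
  structure(list(effects = effects, posthoc = posthoc, alpha = alpha),
            class = "anova_global")
}

#' @export
print.anova_global <- function(x, ...) {
  cat("<anova_global> split-plot ANOVA (group x metric)\n")
  print(x$effects, digits = 4)
  if (!is.null(x$posthoc)) {
    cat("post hoc univariate F-tests:\n")
    print(x$posthoc, digits = 4)
  }
  invisible(x)
}

#' Spearman rank correlation between a clinical variable and a nodal metric
#'
#' Rank correlation with midrank ties and a two-sided p-value. Zero
#' variance in either variable leaves the correlation undefined and is
#' flagged rather than silently propagated.
#'
#' @param clinical,metric paired numeric vectors (NA pairs dropped;
#'   at least 5 complete pairs required).
#' @param variable,node optional labels carried into the result.
#' @return A one-row data.frame: `variable`, `node`, `rho`, `p`, `n`,
#'   `defined`.
#' @export
spearman_correlation <- function(clinical, metric,
                                 variable = NA_character_,
                                 node = NA_character_) {
  keep <- stats::complete.cases(clinical, metric)
  x <- clinical[keep]; y <- metric[keep]
  if (length(x) < 5) stop("need at least 5 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(data.frame(variable = variable, node = node, rho = NA_real_,
                      p = NA_real_, n = length(x), defined = FALSE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  data.frame(variable = variable, node = node,
             rho = unname(ct$estimate), p = ct$p.value, n = length(x),
             defined = TRUE)
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' The classic two-sample t statistic computed from `(mean, SD, n)` pairs,
#' for comparing published demographic summaries when raw values are
#' unavailable.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return A list: `t`, `df`, `p` (two-sided).
#' @export
pooled_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean1 - mean2) / se
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Demographic comparison of two clinical tables
#'
#' Two-sample t tests (pooled variance by default, Welch optionally) for
#' continuous variables and Fisher's exact test for categorical variables,
#' as appropriate per variable. Variables entirely missing in either group
#' are skipped.
#'
#' @param clinical_a,clinical_b clinical data.frames (as produced by
#'   [generate_cohort()]).
#' @param continuous continuous variable names.
#' @param categorical categorical variable names.
#' @param var_equal use the pooled-variance t test (default TRUE).
#' @return A data.frame: `variable`, `test`, `statistic`, `p`.
#' @export
demographics_compare <- function(clinical_a, clinical_b,
                                 continuous = c("age", "onset_age",
                                                "duration",
                                                "bfm_movement",
                                                "bfm_disability"),
                                 categorical = "sex",
                                 var_equal = TRUE) {
  if (nrow(clinical_a) < 2 || nrow(clinical_b) < 2)
    stop("each group needs at least 2 subjects")
  rows <- list()
  for (v in continuous) {
    xa <- clinical_a[[v]]; xb <- clinical_b[[v]]
    if (is.null(xa) || is.null(xb) || all(is.na(xa)) || all(is.na(xb)))
      next
    tt <- stats::t.test(xa, xb, var.equal = var_equal)
    rows[[v]] <- data.frame(variable = v,
                            test = if (var_equal) "t_pooled" else "t_welch",
                            statistic = unname(tt$statistic),
                            p = tt$p.value)
  }
  for (v in categorical) {
    xa <- clinical_a[[v]]; xb <- clinical_b[[v]]
    if (is.null(xa) || is.null(xb)) next
    tab <- table(group = rep(c("a", "b"), c(length(xa), length(xb))),
                 value = c(xa, xb))
    ft <- stats::fisher.test(tab)
    rows[[v]] <- data.frame(variable = v, test = "fisher_exact",
                            statistic = NA_real_, p = ft$p.value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter results at a significance threshold
#'
#' Retains rows with `p <= alpha` (boundary inclusive). The default
#' `alpha = 0.016` is the 0.05 level Bonferroni-corrected over the three
#' nodal metrics (degree, strength, betweenness).
#'
#' @param results data.frame with a `p` column.
#' @param alpha significance threshold.
#' @return The retained rows.
#' @export
significance_filter <- function(results, alpha = 0.016) {
  if (!("p" %in% names(results))) stop("results must carry a p column")
  results[!is.na(results$p) & results$p <= alpha, , drop = FALSE]
}
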