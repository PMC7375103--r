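two_cliques <- function(k = 5, bridge = 1) {
  w <- matrix(0, 2 * k, 2 * k)
  w[1:k, 1:k] <- 1
  w[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1
  diag(w) <- 0
  w[k, k + 1] <- w[k + 1, k] <- bridge
  w
}

test_that("modularity of canonical partitions matches closed forms", {
  w <- two_cliques(5, bridge = 0)  # two disjoint 5-cliques
  net <- toy_net(w)
  split <- rep(1:2, each = 5)
  expect_equal(modularity_q(net, setNames(split, rownames(w))), 0.5)
  # trivial one-block partition has Q = 0 exactly
  expect_equal(modularity_q(net, setNames(rep(1, 10), rownames(w))), 0)
  # agreement with the independent igraph implementation
  set.seed(12)
  wr <- random_connected_graph(9)
  g <- igraph::graph_from_adjacency_matrix(wr, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  assign <- sample(1:3, 9, replace = TRUE)
  expect_equal(modularity_q(toy_net(wr), setNames(assign,
                                                  rownames(toy_net(wr)$weights))),
               igraph::modularity(g, assign, weights = igraph::E(g)$weight),
               tolerance = 1e-12)
})

test_that("consensus Louvain splits two bridged cliques and recomputes Q
           from the assignment", {
  w <- two_cliques(5)
  net <- toy_net(w)
  part <- louvain_partition(net, n_iterations = 25, seed = 3)
  expect_equal(part$n_modules, 2)
  expect_equal(unname(part$assignment[1:5]), rep(part$assignment[[1]], 5))
  expect_equal(unname(part$assignment[6:10]), rep(part$assignment[[6]], 5))
  # hand-evaluated Newman-Girvan Q of the clique split: 2(20/42 - (21/42)^2)
  expect_equal(part$q, 2 * (20 / 42 - (21 / 42)^2))
  expect_equal(part$q, modularity_q(net, part$assignment))
  expect_length(part$iteration_qs, 25)
  # the consensus Q is at least that of the trivial partition (= 0)
  expect_gt(part$q, 0)
  expect_error(louvain_partition(toy_net(matrix(0, 4, 4))), "edgeless")
})

test_that("a complete graph yields a single community and no split beats
           Q = 0", {
  full <- matrix(1, 8, 8); diag(full) <- 0
  part <- louvain_partition(toy_net(full), n_iterations = 20, seed = 1)
  expect_equal(part$n_modules, 1)
  for (i in 1:20) {
    split <- sample(1:3, 8, replace = TRUE)
    expect_lte(modularity_q(toy_net(full),
                            setNames(split, rownames(full))), 0 + 1e-12)
  }
})

test_that("consensus partitions are stable across outer seeds on planted
           modular networks", {
  cfg <- cohort_config(groups = c(controls = 6L), seed = 2L)
  co <- generate_cohort(cfg)
  ga <- group_average(build_networks(co$subjects), group = "controls")
  parts <- lapply(1:8, function(s)
    louvain_partition(ga, n_iterations = 40, seed = s)$assignment)
  agreements <- vapply(parts[-1], function(p)
    mclust::adjustedRandIndex(p, parts[[1]]), 0)
  expect_gte(mean(agreements == 1), 0.95)
})

test_that("participation coefficients match direct summation", {
  # all edges inside own module
  w <- two_cliques(4, bridge = 0)
  modules <- setNames(rep(1:2, each = 4), rownames(toy_net(w)$weights))
  expect_equal(unname(participation_coefficient(toy_net(w), modules)),
               rep(0, 8))
  # degree-4 node, 2 edges in each of two modules -> 0.5
  w2 <- edge_matrix(6, list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1),
                            c(1, 5, 1)))
  mod2 <- setNames(c(1, 1, 1, 2, 2, 2), sprintf("R%02d", 1:6))
  expect_equal(unname(participation_coefficient(toy_net(w2), mod2))[1],
               1 - (0.5^2 + 0.5^2))
  # degree-4 node, one edge in each of 4 modules -> 0.75
  mod4 <- setNames(c(1, 1, 2, 3, 4, 4), sprintf("R%02d", 1:6))
  expect_equal(unname(participation_coefficient(toy_net(w2), mod4))[1],
               1 - 4 * 0.25^2)
  # brute-force agreement on random graphs, and the 1 - 1/M ceiling
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(4:7, 1)
    w <- random_connected_graph(n, 0.7)
    m <- sample(1:3, n, replace = TRUE)
    pc <- participation_coefficient(toy_net(w),
                                    setNames(m, rownames(toy_net(w)$weights)))
    expect_equal(unname(pc), brute_participation(w, m), tolerance = 1e-12)
    expect_true(all(pc <= 1 - 1 / length(unique(m)) + 1e-12))
    expect_true(all(pc >= 0))
  }
})

test_that("hub identification applies the mean + 1 sample-SD rule per
           basis", {
  # star-like construction: degrees {3, 3, 3, 9}; sample SD = 3
  w <- matrix(0, 10, 10)
  w[1, 2:10] <- w[2:10, 1] <- 1   # node 1: degree 9
  w[2, 3] <- w[3, 2] <- 1; w[4, 5] <- w[5, 4] <- 1
  net <- toy_net(w)
  deg <- nodal_degree(net)
  thr <- mean(deg) + sd(deg)
  part <- setNames(rep(1, 10), rownames(w))
  hubs <- identify_hubs(net, part)
  expect_setequal(hubs$node[hubs$basis == "degree"],
                  names(deg)[deg >= thr])
  # values {10, 10, 10, 30}: mean 15, sample SD 10 -> only the 30 is a hub
  vals <- c(10, 10, 10, 30)
  expect_equal(vals >= mean(vals) + sd(vals), c(FALSE, FALSE, FALSE, TRUE))
  # degenerate SD = 0: no hubs at all
  full <- matrix(1, 5, 5); diag(full) <- 0
  expect_equal(nrow(identify_hubs(toy_net(full),
                                  setNames(rep(1, 5), rownames(full)))), 0)
})

test_that("hub sets are invariant to global weight rescaling", {
  set.seed(31)
  w <- random_connected_graph(20, 0.4)
  part <- setNames(sample(1:3, 20, replace = TRUE),
                   rownames(toy_net(w)$weights))
  h1 <- identify_hubs(toy_net(w), part)
  h2 <- identify_hubs(toy_net(w * 7.3), part)
  expect_equal(h1[, c("node", "basis", "module", "klass")],
               h2[, c("node", "basis", "module", "klass")])
})

test_that("hub classes follow the participation-coefficient bands", {
  expect_equal(classify_hub(c(0.2, 0.3, 0.5, 0.75, 0.8)),
               c("provincial", "provincial", "connector", "connector",
                 "unclassified"))
  expect_equal(classify_hub(0.2, convention = "inverted"), "connector")
  expect_equal(classify_hub(0.5, convention = "inverted"), "provincial")
  expect_error(classify_hub(1.2), "\\[0, 1\\]")
})

test_that("module matching maximizes total overlap (exhaustive oracle)", {
  a <- setNames(rep(1:5, each = 6), sprintf("N%02d", 1:30))
  # identical partitions match as the identity with full overlap
  m <- match_modules(a, a)
  expect_equal(m$pairs$module_a, m$pairs$module_b)
  expect_equal(m$pairs$overlap, rep(6L, 5))
  # one relabeled node keeps the matching, reduces one overlap
  b <- a; b["N01"] <- 2
  m2 <- match_modules(a, b)
  expect_equal(m2$pairs$module_a, m2$pairs$module_b)
  expect_equal(sum(m2$pairs$overlap), 29)
  # random relabelings: equal to brute-force search over all 5! pairings
  set.seed(41)
  for (rep in 1:10) {
    b <- setNames(sample(1:5, 30, replace = TRUE), names(a))
    got <- match_modules(a, b)
    tab <- table(a, b)
    best <- -1
    perm_rec <- function(rem, acc) {
      if (!length(rem)) {
        score <- sum(tab[cbind(seq_len(5), acc)])
        if (score > best) best <<- score
        return()
      }
      for (x in rem) perm_rec(setdiff(rem, x), c(acc, x))
    }
    perm_rec(seq_len(ncol(tab)), integer())
    expect_equal(sum(got$pairs$overlap), best)
  }
})

test_that("module migration reports signed percent size changes and moved
           nodes", {
  a <- setNames(rep(1:2, c(14, 16)), sprintf("N%02d", 1:30))
  m0 <- module_migration(a, a)
  expect_equal(m0$module_size_changes$percent_change, c(0, 0))
  expect_equal(nrow(m0$migrations), 0)
  # a 14-node module losing one node: -7.14%
  b <- a; b["N01"] <- 2
  m1 <- module_migration(a, b)
  chg <- m1$module_size_changes
  expect_equal(chg$percent_change[chg$module_a == 1], -1 / 14 * 100)
  expect_equal(round(chg$percent_change[chg$module_a == 1]), -7)
  expect_equal(m1$migrations$node, "N01")
  expect_equal(m1$migrations$from, 1L)
  expect_equal(m1$migrations$to, 2L)
  # a 15-node module gaining three nodes: +20%
  a2 <- setNames(rep(1:2, c(15, 15)), sprintf("N%02d", 1:30))
  b2 <- a2; b2[c("N16", "N17", "N18")] <- 1
  m2 <- module_migration(a2, b2)
  chg2 <- m2$module_size_changes
  expect_equal(chg2$percent_change[chg2$module_a == 1], 20)
})

test_that("hub comparison partitions hubs into shared, gained, lost and
           status changes", {
  ha <- data.frame(node = c("Ins_L", "Put_R", "PCC_R"),
                   basis = c("degree", "degree", "strength"),
                   value = c(51.3, 65.8, 57.6),
                   module = c(3L, 5L, 3L),
                   participation = c(0.5, 0.6, 0.4),
                   klass = c("connector", "connector", "connector"))
  expect_equal(nrow(compare_hubs(ha, ha)$status_changes), 0)
  expect_equal(nrow(compare_hubs(ha, ha)$shared), 3)

  hb <- data.frame(node = c("Put_R", "PCC_R", "SFG_R"),
                   basis = c("degree", "strength", "degree"),
                   value = c(73.0, 56.4, 55.5),
                   module = c(5L, 3L, 2L),
                   participation = c(0.6, 0.2, 0.5),
                   klass = c("connector", "provincial", "connector"))
  cmp <- compare_hubs(ha, hb)
  expect_equal(cmp$lost$node, "Ins_L")
  expect_equal(cmp$gained$node, "SFG_R")
  expect_equal(cmp$status_changes$node, "PCC_R")
  expect_equal(cmp$status_changes$from_klass, "connector")
  expect_equal(cmp$status_changes$to_klass, "provincial")
  expect_equal(intersect(paste(cmp$gained$node, cmp$gained$basis),
                         paste(cmp$lost$node, cmp$lost$basis)),
               character())
})
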