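test_that("generators are seed-deterministic", {
  expect_identical(simulate_tree(40, seed = 3, n_long_branches = 5),
                   simulate_tree(40, seed = 3, n_long_branches = 5))
  expect_false(identical(simulate_tree(40, seed = 3), simulate_tree(40, 4)))
  expect_identical(simulate_uniform_dataset(n_samples = 6, n_otus = 30,
                                            depth_range = c(100, 500),
                                            seed = 5),
                   simulate_uniform_dataset(n_samples = 6, n_otus = 30,
                                            depth_range = c(100, 500),
                                            seed = 5))
  expect_identical(monoculture_template(seed = 2),
                   monoculture_template(seed = 2))
})

test_that("generated trees and tables pass the validators", {
  sim <- simulate_uniform_dataset(n_samples = 8, n_otus = 50,
                                  depth_range = c(200, 1000), seed = 7)
  expect_silent(unifracx:::validate_tree(sim$tree))
  m <- as.matrix(sim$table[, -1])
  expect_true(all(m >= 0 & m == round(m)))
  expect_true(all(rowSums(m) >= 200 & rowSums(m) <= 1000))
  expect_setequal(colnames(m), sim$tree$tip.label)
})

test_that("monoculture simulation shuffles one template into three groups", {
  tmpl <- monoculture_template(n_otus = 115, dominant_prop = 0.97,
                               total = 10000, seed = 1)
  expect_equal(sum(tmpl), 10000)
  expect_equal(unname(tmpl["OTU_1"]), 9700)

  doms <- c("OTU_7", "OTU_42", "OTU_99")
  sim <- simulate_monocultures(tmpl, doms, group_size = 20, seed = 1)
  m <- as.matrix(sim$table[, -1])
  expect_equal(dim(m), c(60, 115))
  expect_equal(nrow(sim$groups), 60)
  expect_equal(as.integer(table(sim$groups$group)), rep(20L, 3))
  for (i in seq_len(nrow(m))) {
    # same multiset of counts as the template, total conserved
    expect_equal(sort(m[i, ]), sort(unname(tmpl)), ignore_attr = TRUE)
    # the group's dominant OTU holds the maximum count
    expect_equal(unname(m[i, sim$groups$dominant_otu[i]]), max(m[i, ]))
  }
  expect_error(simulate_monocultures(tmpl, c("OTU_7", "nope", "OTU_9")),
               "nope")
})

test_that("boundary cases realize their advertised distances", {
  cases <- unifrac_boundary_cases()
  expect_named(cases, c("disjoint", "half_shared", "identical"))
  for (case in cases) {
    expect_equal(unweighted_unifrac(case$tree, case$counts_a, case$counts_b),
                 case$expected)
  }
})

test_that("long-branch instance has a genuinely bistable rare OTU", {
  sim <- simulate_longbranch_flip(seed = 2)
  # exact hypergeometric zero probability, cross-checked term by term
  n_tot <- 1075; k <- 5; d <- 221
  p_manual <- prod((n_tot - d - seq_len(k) + 1) / (n_tot - seq_len(k) + 1))
  expect_equal(sim$p_zero, p_manual, tolerance = 1e-12)
  expect_gt(sim$p_zero, 0.2)
  expect_lt(sim$p_zero, 0.8)

  pend <- sim$tree$edge[, 2] <= ape::Ntip(sim$tree)
  flag_edge <- which(pend &
    sim$tree$tip.label[pmin(sim$tree$edge[, 2], ape::Ntip(sim$tree))] ==
      sim$flagged_otu)
  expect_gte(sim$tree$edge.length[flag_edge],
             5 * median(sim$tree$edge.length))

  m <- as.matrix(sim$table[, -1])
  rownames(m) <- sim$table$sample_id
  expect_equal(unname(rowSums(m)), c(1075, 221))
  expect_equal(unname(m["A", sim$flagged_otu]), 5)

  expect_error(simulate_longbranch_flip(flagged_count = 50, seed = 1),
               "infeasible")
})

test_that("rarefaction instances destabilize unweighted more than weighted
           on the long-branch pattern", {
  sim <- simulate_longbranch_flip(seed = 4)
  tr <- sim$tree
  rel_diff <- function(metric) {
    vapply(1:50, function(s) {
      d1 <- as.matrix(distance_matrix(sim$table, tr, metric,
                                      rarefy_first = TRUE, seed = 2 * s))
      d2 <- as.matrix(distance_matrix(sim$table, tr, metric,
                                      rarefy_first = TRUE, seed = 2 * s + 1))
      tot <- d1[1, 2] + d2[1, 2]
      if (tot == 0) 0 else abs(d1[1, 2] - d2[1, 2]) / (tot / 2)
    }, numeric(1))
  }
  expect_gt(mean(rel_diff("unweighted")), mean(rel_diff("weighted")))
})

test_that("uniform generator draws all samples from one composition", {
  sim <- simulate_uniform_dataset(n_samples = 6, n_otus = 120,
                                  depth_range = c(1e6, 1e6),
                                  n_long_branches = 0, seed = 11)
  expect_equal(sum(sim$composition), 1)
  # at extreme equal depth, weighted UniFrac between any two samples is
  # negligible: there is no structure to find
  d <- as.matrix(distance_matrix(sim$table, sim$tree, "weighted"))
  expect_lt(max(d), 0.01)
})

test_that("two-group generator separates groups exactly when asked to", {
  sim0 <- simulate_two_group_dataset(n_per_group = 4, n_otus = 40,
                                     effect_size = 0, seed = 13)
  expect_equal(sim0$composition["group1", ], sim0$composition["group2", ])

  sim <- simulate_two_group_dataset(n_per_group = 10, n_otus = 60,
                                    effect_size = 0.9,
                                    depth_range = c(1000, 5000), seed = 13)
  expect_length(sim$groups, 20)
  for (metric in c("unweighted", "weighted", "information", "ratio",
                   "braycurtis")) {
    d <- distance_matrix(sim$table, sim$tree, metric, rarefy_first = FALSE,
                         intersect_taxa = TRUE)
    pc1 <- pcoa(d)$points[, 1]
    g1 <- pc1[sim$groups == "group1"]
    g2 <- pc1[sim$groups == "group2"]
    gap <- abs(mean(g1) - mean(g2))
    spread <- max(max(g1) - min(g1), max(g2) - min(g2))
    expect_gt(gap, spread)
  }
})
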