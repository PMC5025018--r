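test_that("information weight follows the entropy curve", {
  expect_equal(information_weight(c(0, 0.5, 1)), c(0, 0.5, 0))
  expect_error(information_weight(1.2), "0, 1")

  # in the low-abundance range the curve lies above the identity weighting
  # and rises faster from zero
  set.seed(7)
  p <- runif(200, 1e-6, 0.2)
  expect_true(all(information_weight(p) > p))
  expect_true(all(information_weight(p) / p > 1))
})

test_that("unweighted UniFrac realizes its boundary values", {
  for (case in unifrac_boundary_cases()) {
    expect_identical(
      unweighted_unifrac(case$tree, case$counts_a, case$counts_b),
      case$expected)
  }
})

test_that("weighted UniFrac matches hand evaluations", {
  tr <- parse_newick("(A:1,B:1);")
  expect_equal(weighted_unifrac(tr, c(A = 1, B = 0), c(A = 0, B = 1)), 1)
  p <- c(A = 0.3, B = 0.7)
  expect_equal(weighted_unifrac(tr, p, p), 0)

  # equal proportional shifts carry equal weight regardless of baseline
  lo <- weighted_unifrac(tr, c(A = 0.005, B = 0.995),
                         c(A = 0.010, B = 0.990))
  hi <- weighted_unifrac(tr, c(A = 0.095, B = 0.905),
                         c(A = 0.100, B = 0.900))
  expect_equal(lo, hi, tolerance = 1e-12)
})

test_that("information UniFrac vanishes at abundance extremes", {
  tr <- parse_newick("(A:1,B:1);")
  expect_equal(information_unifrac(tr, c(A = 0.5, B = 0.5), c(A = 1, B = 0)),
               0.5)
  # two distinct pure monocultures are indistinguishable to it
  expect_equal(information_unifrac(tr, c(A = 1, B = 0), c(A = 0, B = 1)), 0)
})

test_that("ratio UniFrac is zero on identical input and symmetric", {
  tr <- parse_newick("((A:1,B:1):1,C:1);")
  u <- c(A = 1, B = 1, C = 1) / 3
  expect_equal(ratio_unifrac(tr, u, u), 0)

  set.seed(17)
  for (rep in 1:10) {
    trr <- random_tree(6)
    a <- random_positive_props(trr)
    b <- random_positive_props(trr)
    expect_equal(ratio_unifrac(trr, a, b), ratio_unifrac(trr, b, a),
                 tolerance = 1e-12)
  }
  expect_error(ratio_unifrac(tr, c(A = 1, B = 0, C = 0), u), "replace_zeros")
})

test_that("Bray-Curtis matches the count formula", {
  expect_equal(bray_curtis(c(x = 5, y = 2), c(x = 5, y = 2)), 0)
  expect_equal(bray_curtis(c(x = 5, y = 0), c(x = 0, y = 9)), 1)
  expect_equal(bray_curtis(c(x = 6, y = 2), c(x = 2, y = 2)), 1 / 3)
})

test_that("all four UniFrac weightings match the enumeration oracles", {
  set.seed(23)
  for (rep in 1:40) {
    tr <- random_tree(sample(3:10, 1))
    a <- random_counts(tr)
    b <- random_counts(tr)
    expect_equal(unweighted_unifrac(tr, a, b), oracle_unweighted(tr, a, b),
                 tolerance = 1e-10)
    expect_equal(weighted_unifrac(tr, a, b), oracle_weighted(tr, a, b),
                 tolerance = 1e-10)
    expect_equal(information_unifrac(tr, a, b),
                 oracle_information(tr, a, b), tolerance = 1e-10)
    ap <- random_positive_props(tr)
    bp <- random_positive_props(tr)
    expect_equal(ratio_unifrac(tr, ap, bp), oracle_ratio(tr, ap, bp),
                 tolerance = 1e-10)
  }
})

test_that("distance_matrix agrees with the pairwise front ends", {
  set.seed(29)
  tr <- random_tree(12)
  m <- t(vapply(1:4, function(i) random_counts(tr, sparsity = 0.3),
                numeric(12)))
  rownames(m) <- paste0("s", 1:4)
  for (metric in c("unweighted", "weighted", "information", "braycurtis")) {
    d <- as.matrix(distance_matrix(m, tr, metric, rarefy_first = FALSE))
    expect_equal(unname(diag(d)), rep(0, 4))
    expect_identical(d, t(d))
    pairfun <- switch(metric,
      unweighted = function(a, b) unweighted_unifrac(tr, a, b),
      weighted = function(a, b) weighted_unifrac(tr, a, b),
      information = function(a, b) information_unifrac(tr, a, b),
      braycurtis = bray_curtis)
    expect_equal(d["s1", "s3"], pairfun(m[1, ], m[3, ]), tolerance = 1e-12)
  }
  # ratio goes through shared zero replacement; check against the oracle on
  # the replaced proportions
  dr <- as.matrix(distance_matrix(m, tr, "ratio", rarefy_first = FALSE))
  zz <- as.matrix(replace_zeros(m)[, -1])
  rownames(zz) <- rownames(m)
  colnames(zz) <- colnames(m)
  expect_equal(dr["s1", "s3"], oracle_ratio(tr, zz["s1", ], zz["s3", ]),
               tolerance = 1e-10)
})

test_that("distance_matrix handles labels, permutations and degenerate sizes", {
  tr <- parse_newick("((A:1,B:1):1,C:1);")
  one <- matrix(c(3, 1, 0), 1, dimnames = list("only", c("A", "B", "C")))
  d1 <- as.matrix(distance_matrix(one, tr, "weighted"))
  expect_equal(unname(d1), matrix(0, 1, 1))

  m <- rbind(s1 = c(A = 5, B = 0, C = 1), s2 = c(A = 0, B = 2, C = 2),
             s3 = c(A = 1, B = 1, C = 1))
  d <- as.matrix(distance_matrix(m, tr, "weighted"))
  dp <- as.matrix(distance_matrix(m[c(3, 1, 2), ], tr, "weighted"))
  expect_equal(dp[rownames(d), colnames(d)], d)

  bad <- rbind(s1 = c(A = 1, X = 1))
  expect_error(distance_matrix(bad, tr, "weighted"), "absent.*X")
  expect_equal(
    as.matrix(distance_matrix(bad, tr, "weighted", intersect_taxa = TRUE)),
    matrix(0, 1, 1, dimnames = list("s1", "s1")))
})

test_that("tree leaves missing from the table widen only the normalizer", {
  tr <- parse_newick("((A:1,B:1):1,C:1);")
  tr_extra <- parse_newick("(((A:1,B:1):1,C:1):0.5,D:2);")
  m <- rbind(s1 = c(A = 5, B = 1), s2 = c(A = 1, B = 5))
  w <- weighted_unifrac(tr, m[1, ], m[2, ])
  w_extra <- as.matrix(distance_matrix(m, tr_extra, "weighted"))[1, 2]
  expect_equal(w_extra, w * sum(tr$edge.length) / sum(tr_extra$edge.length),
               tolerance = 1e-12)
})

test_that("metric axioms hold without pruning and fail with it", {
  set.seed(31)
  for (rep in 1:30) {
    tr <- random_tree(sample(4:10, 1))
    trip <- lapply(1:3, function(i) random_counts(tr, sparsity = 0.3))
    m <- do.call(rbind, trip)
    rownames(m) <- c("x", "y", "z")
    for (metric in c("unweighted", "weighted")) {
      d <- as.matrix(distance_matrix(m, tr, metric, rarefy_first = FALSE))
      expect_true(all(d >= 0))
      expect_identical(d, t(d))
      expect_lte(d["x", "z"], d["x", "y"] + d["y", "z"] + 1e-12)
    }
  }

  inst <- pruning_violation_instance()
  dp <- as.matrix(distance_matrix(inst$counts, inst$tree, "weighted",
                                  prune = TRUE))
  expect_gt(dp["A", "C"], dp["A", "B"] + dp["B", "C"] + 1e-6)
})

test_that("uf_dist objects carry flags and tidy/round-trip cleanly", {
  inst <- pruning_violation_instance()
  d <- distance_matrix(inst$counts, inst$tree, "weighted")
  expect_true(d$is_metric)
  dp <- distance_matrix(inst$counts, inst$tree, "weighted", prune = TRUE)
  expect_false(dp$is_metric)
  expect_true(dp$pruned)
  dr <- distance_matrix(inst$counts, inst$tree, "ratio")
  expect_false(dr$is_metric)

  td <- tidy(d)
  expect_equal(nrow(td), 3)
  expect_equal(td$distance[td$sample_1 == "A" & td$sample_2 == "C"],
               d$matrix["A", "C"])

  p <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d, p)
  back <- read_distance_matrix(p, metric = "weighted")
  expect_equal(back$matrix, d$matrix, tolerance = 1e-9)
})
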