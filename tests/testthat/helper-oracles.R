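# Independent brute-force oracles. These deliberately avoid the package's
# vectorized branch-mass machinery: subtrees are enumerated leaf by leaf and
# the formulas are evaluated term by term.

oracle_subtree_leaves <- function(tree, node) {
  n_tip <- ape::Ntip(tree)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, oracle_subtree_leaves, tree = tree))
}

oracle_full_props <- function(tree, p) {
  full <- stats::setNames(rep(0, ape::Ntip(tree)), tree$tip.label)
  full[names(p)] <- p
  full
}

oracle_branch_masses <- function(tree, p) {
  p <- oracle_full_props(tree, p)
  vapply(seq_len(nrow(tree$edge)), function(i) {
    sum(p[oracle_subtree_leaves(tree, tree$edge[i, 2])])
  }, numeric(1))
}

oracle_unweighted <- function(tree, a, b) {
  in_a <- oracle_branch_masses(tree, a / sum(a)) > 0
  in_b <- oracle_branch_masses(tree, b / sum(b)) > 0
  bl <- tree$edge.length
  sum(bl[(in_a | in_b) & !(in_a & in_b)]) / sum(bl[in_a | in_b])
}

oracle_weighted <- function(tree, a, b) {
  ma <- oracle_branch_masses(tree, a / sum(a))
  mb <- oracle_branch_masses(tree, b / sum(b))
  sum(tree$edge.length * abs(ma - mb)) / sum(tree$edge.length)
}

oracle_information <- function(tree, a, b) {
  iw <- function(p) ifelse(p > 0, -p * log2(p), 0)
  ma <- oracle_branch_masses(tree, a / sum(a))
  mb <- oracle_branch_masses(tree, b / sum(b))
  sum(tree$edge.length * abs(iw(ma) - iw(mb))) / sum(tree$edge.length)
}

# ratio UniFrac: for each branch, the collapsed composition is the subtree's
# combined proportion plus every outside leaf's own proportion; gm is the
# literal product^(1/n).
oracle_ratio <- function(tree, a, b) {
  one <- function(p) {
    p <- oracle_full_props(tree, p / sum(p))
    vapply(seq_len(nrow(tree$edge)), function(i) {
      inside <- oracle_subtree_leaves(tree, tree$edge[i, 2])
      parts <- c(sum(p[inside]), p[setdiff(tree$tip.label, inside)])
      gm <- prod(parts)^(1 / length(parts))
      sum(p[inside]) / gm
    }, numeric(1))
  }
  sum(tree$edge.length * abs(one(a) - one(b))) / sum(tree$edge.length)
}

oracle_bray <- function(a, b) {
  1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
}

# brute-force 2-D Procrustes: scan rotation angle (both reflections), with
# the optimal scale and translation in closed form given the rotation
oracle_procrustes_disparity <- function(reference, target) {
  xc <- sweep(reference, 2, colMeans(reference))
  yc <- sweep(target, 2, colMeans(target))
  resid <- function(theta, reflect) {
    r <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    if (reflect) r <- r %*% diag(c(1, -1))
    yr <- yc %*% r
    s <- sum(xc * yr) / sum(yr^2)
    sum((xc - s * yr)^2)
  }
  best <- Inf
  for (reflect in c(FALSE, TRUE)) {
    for (start in seq(0, 2 * pi, length.out = 13)[-13]) {
      o <- stats::optimize(resid, c(start - 0.3, start + 0.3),
                           reflect = reflect, tol = 1e-12)
      best <- min(best, o$objective)
    }
  }
  best / sum(xc^2)
}

# -- random instance generators ----------------------------------------------

random_tree <- function(n, zero_lengths = FALSE) {
  tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 2)
  if (zero_lengths) {
    k <- sample(nrow(tr$edge), 1)
    tr$edge.length[k] <- 0
  }
  tr
}

random_counts <- function(tree, sparsity = 0.4) {
  n <- ape::Ntip(tree)
  repeat {
    x <- stats::rpois(n, 5) * stats::rbinom(n, 1, 1 - sparsity)
    if (sum(x) > 0) break
  }
  stats::setNames(x, tree$tip.label)
}

random_positive_props <- function(tree) {
  x <- stats::rgamma(ape::Ntip(tree), shape = 0.7) + 1e-4
  stats::setNames(x / sum(x), tree$tip.label)
}

# partition recovery: TRUE iff hierarchical clustering at k groups matches
# the labels exactly up to label permutation
recovers_groups <- function(d, labels, k = length(unique(labels)),
                            method = "average") {
  cl <- stats::cutree(stats::hclust(stats::as.dist(d), method = method),
                      k = k)
  tab <- table(cl, labels)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "unifracx", mustWork = TRUE)
}

fixture_counts <- function() {
  read_count_table(fixture_path("longbranch_rarefaction_counts.tsv"))
}

fixture_tree <- function() {
  parse_newick(fixture_path("longbranch_tree_synthetic.nwk"))
}

# the 3-sample configuration on which per-pair tree pruning breaks the
# triangle inequality for weighted UniFrac: two monocultures on distant
# leaves plus a mixed sample touching a third leaf
pruning_violation_instance <- function() {
  tree <- parse_newick("((L1:1,L2:1):5,L3:1);")
  counts <- matrix(c(100, 0, 0,
                     45, 45, 10,
                     0, 100, 0),
                   3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"), c("L1", "L2", "L3")))
  list(tree = tree, counts = counts)
}
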