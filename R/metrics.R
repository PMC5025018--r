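# All four UniFrac weightings reduce to a branch-length-weighted L1 distance
# between per-branch transformed masses; only the transform differs:
#   unweighted  : 1{mass > 0}, then ratio of symmetric difference to union
#   weighted    : identity
#   information : m -> -m * log2(m)          (0 log 0 := 0)
#   ratio       : m -> m / gm(collapsed composition at that branch)
# Each is normalized by the sum of ALL branch lengths of the (un-pruned)
# tree, exactly as the formulas are written; this differs from the
# abundance-weighted normalization of the 2007 weighted UniFrac.

UF_METRICS <- c("unweighted", "weighted", "information", "ratio", "braycurtis")

#' Shannon information weight of a proportion
#'
#' `I(p) = -p * log2(p)` (bits), with `I(0) = 0` by the usual entropy limit
#' convention. Zero at both abundance extremes and maximal at `p = 1/e`; the
#' information UniFrac weighting applies this transform to every branch mass,
#' which is why that metric mutes taxa at very high or very low abundance and
#' is steeper than the identity weighting below roughly 0.2.
#'
#' @param p Numeric vector of proportions in \[0, 1\].
#' @return `-p * log2(p)` in bits.
#' @examples
#' information_weight(c(0, 0.5, 1))
#' @export
information_weight <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- -p[pos] * log2(p[pos])
  out
}

# -- single-pair front ends ---------------------------------------------------

check_pair <- function(a, b) {
  if (all(a == 0) || all(b == 0)) {
    stop("each sample needs at least one positive count", call. = FALSE)
  }
}

pair_matrix <- function(tree, a, b, names = c("A", "B")) {
  if (is.null(names(a)) || is.null(names(b))) {
    stop("count/proportion vectors must be named by OTU", call. = FALSE)
  }
  otus <- union(names(a), names(b))
  m <- rbind(a[otus], b[otus])
  m[is.na(m)] <- 0
  dimnames(m) <- list(names, otus)
  missing <- setdiff(otus[colSums(m) > 0], tree$tip.label)
  if (length(missing)) {
    stop("OTU(s) absent from the tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Unweighted UniFrac between two samples
#'
#' The sum of branch lengths belonging to exactly one of the two samples,
#' divided by the sum of branch lengths belonging to at least one. A branch
#' belongs to a sample when at least one OTU in the leaves below it has a
#' non-zero abundance. 0 means identical taxon sets, 1 means no shared
#' branches.
#'
#' @param tree A rooted [ape::phylo] tree covering all observed OTUs.
#' @param counts_a,counts_b Named non-negative count (or presence) vectors.
#' @return Dissimilarity in \[0, 1\].
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' unweighted_unifrac(tr, c(A = 5, B = 1), c(C = 2, D = 9)) # disjoint -> 1
#' @export
unweighted_unifrac <- function(tree, counts_a, counts_b) {
  check_pair(counts_a, counts_b)
  m <- pair_matrix(tree, counts_a, counts_b)
  mass <- branch_mass_matrix(tree, m / rowSums(m))
  in_a <- mass[, 1] > 0
  in_b <- mass[, 2] > 0
  b <- tree$edge.length
  sum(b[xor(in_a, in_b)]) / sum(b[in_a | in_b])
}

#' Weighted UniFrac between two samples
#'
#' Each branch length is weighted by the absolute difference in branch mass
#' (proportional abundance of the subtree) between the samples, and the sum
#' is normalized by the total branch length of the tree.
#'
#' @inheritParams unweighted_unifrac
#' @param props_a,props_b Named proportion (or count; counts are closed to
#'   proportions) vectors.
#' @return Non-negative dissimilarity.
#' @export
weighted_unifrac <- function(tree, props_a, props_b) {
  check_pair(props_a, props_b)
  m <- pair_matrix(tree, props_a, props_b)
  mass <- branch_mass_matrix(tree, m / rowSums(m))
  sum(tree$edge.length * abs(mass[, 1] - mass[, 2])) / sum(tree$edge.length)
}

#' Information UniFrac between two samples
#'
#' Weighted UniFrac on information-transformed branch masses: each branch
#' contributes its length times `|I(mass_A) - I(mass_B)|` with
#' `I(p) = -p log2(p)`, normalized by total branch length. Because `I`
#' vanishes at both abundance extremes, near-monocultures are down-weighted.
#'
#' @inheritParams weighted_unifrac
#' @return Non-negative dissimilarity.
#' @export
information_unifrac <- function(tree, props_a, props_b) {
  check_pair(props_a, props_b)
  m <- pair_matrix(tree, props_a, props_b)
  mass <- branch_mass_matrix(tree, m / rowSums(m))
  iw <- information_weight(pmin(mass, 1))
  dim(iw) <- dim(mass)
  sum(tree$edge.length * abs(iw[, 1] - iw[, 2])) / sum(tree$edge.length)
}

#' Ratio UniFrac between two samples
#'
#' Centers each branch mass on the geometric mean of the "collapsed"
#' composition at that branch — the subtree's combined proportional abundance
#' together with the individual proportions of every leaf outside the subtree
#' — and weights each branch length by the absolute difference of the
#' centered values between samples. Requires strictly positive proportions
#' for every leaf: run [replace_zeros()] first.
#'
#' @inheritParams weighted_unifrac
#' @return Non-negative dissimilarity (not a distance: no triangle-inequality
#'   guarantee).
#' @export
ratio_unifrac <- function(tree, props_a, props_b) {
  check_pair(props_a, props_b)
  m <- pair_matrix(tree, props_a, props_b)
  r <- ratio_transform(tree, m / rowSums(m))
  sum(tree$edge.length * abs(r[, 1] - r[, 2])) / sum(tree$edge.length)
}

# m / gm per branch and sample; p_mat is samples x OTUs, strictly positive,
# and must cover every leaf of the tree (the collapsed composition includes
# all leaves outside each subtree).
ratio_transform <- function(tree, p_mat) {
  uncovered <- setdiff(tree$tip.label, colnames(p_mat))
  if (length(uncovered) || any(p_mat <= 0)) {
    stop("ratio UniFrac needs a strictly positive proportion for every ",
         "tree leaf; run replace_zeros() first", call. = FALSE)
  }
  tipp <- tip_value_matrix(tree, p_mat)
  mass <- edge_subtree_sums(tree, tipp)
  log_in <- edge_subtree_sums(tree, log(tipp))
  n_in <- edge_subtree_sums(tree, matrix(1, nrow(tipp), 1))[, 1]
  log_tot <- colSums(log(tipp))
  n_parts <- ape::Ntip(tree) - n_in + 1
  # log gm of {subtree mass} U {proportions of leaves outside the subtree}
  log_gm <- (log(mass) + rep(log_tot, each = nrow(mass)) - log_in) / n_parts
  exp(log(mass) - log_gm)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `1 - 2 * sum(min(a, b)) / (sum(a) + sum(b))`: 0 for identical count
#' vectors, 1 for samples sharing no species. Computed through
#' [vegan::vegdist()].
#'
#' @param counts_a,counts_b Named non-negative count vectors.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(counts_a, counts_b) {
  check_pair(counts_a, counts_b)
  otus <- union(names(counts_a), names(counts_b))
  m <- rbind(counts_a[otus], counts_b[otus])
  m[is.na(m)] <- 0
  as.numeric(vegan::vegdist(m, method = "bray"))
}

# -- full distance matrices ---------------------------------------------------

manhattan_d <- function(mass, b) {
  as.matrix(stats::dist(t(mass * b), method = "manhattan")) / sum(b)
}

metric_matrix <- function(metric, tree, counts, props) {
  switch(metric,
    braycurtis = as.matrix(vegan::vegdist(counts, method = "bray")),
    unweighted = {
      mass <- branch_mass_matrix(tree, props)
      u <- mass > 0
      bu <- tree$edge.length * u
      covered <- colSums(bu)
      shared <- t(bu) %*% u
      both <- outer(covered, covered, "+")
      d <- (both - 2 * shared) / (both - shared)
      diag(d) <- 0
      d
    },
    weighted = manhattan_d(branch_mass_matrix(tree, props), tree$edge.length),
    information = {
      mass <- branch_mass_matrix(tree, props)
      iw <- information_weight(pmin(mass, 1))
      dim(iw) <- dim(mass)
      manhattan_d(iw, tree$edge.length)
    },
    ratio = manhattan_d(ratio_transform(tree, props), tree$edge.length)
  )
}

#' Pairwise dissimilarity matrix for a count table
#'
#' Runs the full per-metric pipeline on a count table and tree: optional
#' seeded rarefaction (by default only for unweighted UniFrac, the metric
#' that assumes a common sequencing depth), closure to proportions,
#' Bayesian-multiplicative zero replacement for ratio UniFrac, then all
#' pairwise dissimilarities. OTUs present in the tree but absent from the
#' table contribute zero mass while their branch lengths still enter the
#' total-branch-length normalizer.
#'
#' With `prune = TRUE` the tree is re-pruned for every sample pair to the
#' OTUs present in that pair (the behaviour of some UniFrac implementations)
#' and proportions are recomputed on the pruned leaf set; the result is then
#' only a dissimilarity — pruning breaks the triangle inequality — and is
#' flagged accordingly.
#'
#' @param table Count table (tibble or samples x OTUs matrix).
#' @param tree A rooted [ape::phylo] tree; not needed for `"braycurtis"`.
#' @param metric One of `"unweighted"`, `"weighted"`, `"information"`,
#'   `"ratio"`, `"braycurtis"`.
#' @param prune Re-prune the tree per sample pair (default `FALSE`).
#' @param rarefy_first Rarefy before computing? Default: only for
#'   `"unweighted"`.
#' @param depth Rarefaction depth (default: minimum sample total).
#' @param seed Seed for rarefaction (required when rarefying).
#' @param zero_method,pseudo Zero-replacement settings for `"ratio"`; see
#'   [replace_zeros()].
#' @param intersect_taxa If `TRUE`, reconcile tree and table up front: prune
#'   the tree to the table's OTUs and drop table OTUs missing from the tree.
#'   Default `FALSE`: a table OTU missing from the tree is an error, and
#'   tree-only leaves keep contributing branch length to the normalizer.
#' @return A `uf_dist` object: the labelled symmetric matrix plus `metric`,
#'   `pruned` and `is_metric` flags. Use [as.matrix()], [as.dist()],
#'   [generics::tidy()] or [ggplot2::autoplot()] on it.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' tab <- matrix(c(5, 0, 3, 2, 0, 4, 1, 1), 2, byrow = TRUE,
#'               dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
#' distance_matrix(tab, tr, "weighted")
#' @export
distance_matrix <- function(table, tree = NULL, metric = UF_METRICS,
                            prune = FALSE, rarefy_first = NULL, depth = NULL,
                            seed = NULL, zero_method = "bayesian",
                            pseudo = 0.5, intersect_taxa = FALSE) {
  metric <- match.arg(metric)
  m <- as_sample_matrix(table)
  if (metric != "braycurtis") {
    if (is.null(tree)) stop("metric '", metric, "' needs a tree",
                            call. = FALSE)
    validate_tree(tree)
    if (intersect_taxa) {
      shared <- intersect(colnames(m), tree$tip.label)
      if (!length(shared)) {
        stop("tree and table share no OTUs", call. = FALSE)
      }
      tree <- prune_to_taxa(tree, shared)
      m <- m[, shared, drop = FALSE]
    }
    missing <- setdiff(colnames(m)[colSums(m) > 0], tree$tip.label)
    if (length(missing)) {
      stop("OTU(s) absent from the tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(rarefy_first)) rarefy_first <- metric == "unweighted"
  if (rarefy_first) {
    if (is.null(seed)) stop("rarefaction requires a seed", call. = FALSE)
    m <- as_sample_matrix(rarefy(m, depth = depth, seed = seed))
  }
  if (any(rowSums(m) == 0)) {
    stop("sample(s) without any positive count: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "), call. = FALSE)
  }
  props <- if (metric == "ratio") {
    as_sample_matrix(replace_zeros(m, method = zero_method, pseudo = pseudo),
                     integer_counts = FALSE)
  } else {
    m / rowSums(m)
  }

  if (prune && metric != "braycurtis") {
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        taxa <- colnames(m)[m[i, ] > 0 | m[j, ] > 0]
        sub <- prune_to_taxa(tree, taxa)
        cc <- m[c(i, j), intersect(colnames(m), sub$tip.label), drop = FALSE]
        pp <- if (metric == "ratio") {
          as_sample_matrix(replace_zeros(cc), integer_counts = FALSE)
        } else {
          cc / rowSums(cc)
        }
        d[i, j] <- d[j, i] <- metric_matrix(metric, sub, cc, pp)[1, 2]
      }
    }
  } else {
    d <- metric_matrix(metric, tree, m, props)
    d <- pmax((d + t(d)) / 2, 0)  # exact symmetry, no float-negative zeros
    diag(d) <- 0
    dimnames(d) <- list(rownames(m), rownames(m))
  }
  new_uf_dist(d, metric = metric, pruned = prune && metric != "braycurtis",
              rarefied = rarefy_first, depth = depth, seed = seed)
}

new_uf_dist <- function(d, metric, pruned = FALSE, rarefied = FALSE,
                        depth = NULL, seed = NULL) {
  structure(
    list(matrix = d, metric = metric, pruned = pruned,
         is_metric = metric %in% c("unweighted", "weighted", "information") &&
           !pruned,
         rarefied = rarefied, depth = depth, seed = seed),
    class = "uf_dist")
}

#' @export
as.matrix.uf_dist <- function(x, ...) x$matrix

#' @export
as.dist.uf_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$matrix, diag = diag, upper = upper)
}

#' @export
print.uf_dist <- function(x, ...) {
  cat(sprintf("%s %s for %d samples%s%s\n", x$metric,
              if (x$is_metric) "distance" else "dissimilarity",
              nrow(x$matrix),
              if (x$pruned) ", per-pair pruned tree" else "",
              if (x$rarefied) sprintf(", rarefied (seed %s)", x$seed) else ""))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Tidy a pairwise dissimilarity matrix
#'
#' @param x A `uf_dist` object.
#' @param ... Unused.
#' @return A tibble with one row per unordered sample pair: `sample_1`,
#'   `sample_2`, `distance`, `metric`.
#' @method tidy uf_dist
#' @export
tidy.uf_dist <- function(x, ...) {
  d <- x$matrix
  idx <- which(upper.tri(d), arr.ind = TRUE)
  tibble::tibble(sample_1 = rownames(d)[idx[, 1]],
                 sample_2 = colnames(d)[idx[, 2]],
                 distance = d[idx], metric = x$metric)
}

#' Heatmap of a dissimilarity matrix
#'
#' @param object A `uf_dist` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot uf_dist
#' @export
autoplot.uf_dist <- function(object, ...) {
  d <- object$matrix
  df <- tidyr::expand_grid(sample_1 = rownames(d), sample_2 = colnames(d))
  df$distance <- as.vector(t(d))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_1, .data$sample_2,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = object$metric) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write / read a labelled square distance matrix as TSV
#'
#' @param x A `uf_dist`, `dist` or square matrix.
#' @param path TSV path.
#' @return `path` (write) or a `uf_dist` (read).
#' @export
write_distance_matrix <- function(x, path) {
  d <- if (inherits(x, "uf_dist")) x$matrix else as.matrix(x)
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @param metric Metric label to attach on read.
#' @export
read_distance_matrix <- function(path, metric = "unknown") {
  df <- utils::read.delim(path, check.names = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  rownames(d) <- df[[1]]
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    stop("matrix in ", path, " is not symmetric", call. = FALSE)
  }
  new_uf_dist(d, metric = metric)
}
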