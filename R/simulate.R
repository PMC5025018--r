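# Synthetic data generators. Each generator is seed-deterministic and emits
# objects that pass the tree/table validators, so every experiment in the
# package runs without external downloads.

#' Simulate a random phylogenetic tree
#'
#' Coalescent-style random topology with exponential branch lengths
#' (mean `mean_branch`); optionally a number of pendant ("long isolated")
#' branches are stretched by `long_branch_factor`, the tree feature that
#' makes unweighted UniFrac unstable under rarefaction.
#'
#' @param n_otus Number of leaves; labels are `OTU_1 ... OTU_n`.
#' @param seed Integer seed.
#' @param n_long_branches Pendant branches to stretch (default 0).
#' @param long_branch_factor Stretch factor (default 10).
#' @param mean_branch Mean branch length (tree units, default 0.1).
#' @return A rooted [ape::phylo] tree.
#' @export
simulate_tree <- function(n_otus, seed, n_long_branches = 0,
                          long_branch_factor = 10, mean_branch = 0.1) {
  stopifnot(n_otus >= 2, n_long_branches <= n_otus)
  withr::with_seed(as.integer(seed), {
    tree <- ape::rcoal(n_otus, tip.label = paste0("OTU_", seq_len(n_otus)))
    tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / mean_branch)
    if (n_long_branches > 0) {
      pendant <- which(tree$edge[, 2] <= n_otus)
      stretch <- sample(pendant, n_long_branches)
      tree$edge.length[stretch] <- tree$edge.length[stretch] *
        long_branch_factor
    }
    tree
  })
}

#' Boundary cases for unweighted UniFrac
#'
#' Three hand-built (tree, sample pair) fixtures realizing the metric's
#' boundary behaviour: samples on disjoint clades (distance exactly 1),
#' samples sharing exactly half of the covered branch length (0.5), and
#' samples with identical taxon sets (0).
#'
#' @return A named list of cases, each with `tree`, `counts_a`, `counts_b`
#'   and `expected`.
#' @examples
#' case <- unifrac_boundary_cases()$disjoint
#' unweighted_unifrac(case$tree, case$counts_a, case$counts_b)
#' @export
unifrac_boundary_cases <- function() {
  list(
    disjoint = list(
      tree = parse_newick("((A:1,B:1):1,(C:1,D:1):1);"),
      counts_a = c(A = 10, B = 5), counts_b = c(C = 7, D = 2),
      expected = 1),
    half_shared = list(
      tree = parse_newick("(A:1,B:1);"),
      counts_a = c(A = 8), counts_b = c(A = 3, B = 3),
      expected = 0.5),
    identical = list(
      tree = parse_newick("((A:1,B:1):1,(C:1,D:1):1);"),
      counts_a = c(A = 10, B = 1, C = 4), counts_b = c(A = 2, B = 6, C = 1),
      expected = 0)
  )
}

#' Template count vector for the monoculture simulator
#'
#' A single near-monoculture sample: one OTU at `dominant_prop` of the
#' reads, the remainder spread sparsely over the other OTUs with a
#' long-tailed profile (many zeros). Defaults mirror an infected-host
#' community: 115 OTUs, 97% dominance.
#'
#' @param n_otus Number of OTUs.
#' @param dominant_prop Proportion of reads in the dominant OTU.
#' @param total Total read count of the template sample.
#' @param seed Integer seed.
#' @return Named integer vector of counts (names `OTU_1 ...`), with the
#'   dominant count in `OTU_1`.
#' @export
monoculture_template <- function(n_otus = 115, dominant_prop = 0.97,
                                 total = 10000, seed = 1) {
  stopifnot(dominant_prop > 0, dominant_prop < 1, n_otus >= 4)
  withr::with_seed(as.integer(seed), {
    dom <- round(total * dominant_prop)
    tail_p <- stats::rlnorm(n_otus - 1, meanlog = 0, sdlog = 2)
    rest <- stats::rmultinom(1, total - dom, tail_p / sum(tail_p))[, 1]
    stats::setNames(c(dom, rest), paste0("OTU_", seq_len(n_otus)))
  })
}

#' Simulate groups of monoculture samples
#'
#' Every sample carries exactly the template's multiset of counts with the
#' taxa shuffled uniformly at random; afterwards the maximal count is swapped
#' into the group's dominant OTU, producing three groups of near-monocultures
#' dominated by three different taxa. Sample totals equal the template total.
#'
#' @param template Named count vector for one sample (see
#'   [monoculture_template()]).
#' @param dominants Character vector of 3 distinct OTU ids from the
#'   template's OTU set, one per group.
#' @param group_size Samples per group (default 20).
#' @param seed Integer seed.
#' @return A list: `table` (count tibble, `3 * group_size` samples) and
#'   `groups` (tibble: sample_id, group, dominant_otu).
#' @export
simulate_monocultures <- function(template, dominants, group_size = 20,
                                  seed = 1) {
  stopifnot(group_size >= 1, length(dominants) == 3,
            !anyDuplicated(dominants))
  missing <- setdiff(dominants, names(template))
  if (length(missing)) {
    stop("dominant OTU(s) not in the template: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  otus <- names(template)
  withr::with_seed(as.integer(seed), {
    rows <- list()
    meta <- list()
    k <- 0
    for (g in seq_along(dominants)) {
      for (r in seq_len(group_size)) {
        k <- k + 1
        x <- stats::setNames(sample(unname(template)), otus)
        imax <- which.max(x)
        idom <- match(dominants[g], otus)
        x[c(imax, idom)] <- x[c(idom, imax)]
        rows[[k]] <- x
        meta[[k]] <- tibble::tibble(
          sample_id = sprintf("g%d_s%02d", g, r),
          group = paste0("group", g), dominant_otu = dominants[g])
      }
    }
  })
  m <- do.call(rbind, rows)
  groups <- dplyr::bind_rows(meta)
  rownames(m) <- groups$sample_id
  list(table = as_count_tibble(m), groups = groups)
}

#' Simulate a long-branch rarefaction-flip instance
#'
#' Builds the data pattern under which unweighted UniFrac is unstable: a tree
#' holding at least one leaf on a pendant branch at least `branch_factor`
#' times the median branch length, and a two-sample table where that leaf has
#' a low count in the deeper sample, so that rarefying to the shallow
#' sample's depth zeroes it in some rarefaction instances but not others.
#' The zero probability is computed exactly from the hypergeometric tail and
#' required to lie in `(0.2, 0.8)`.
#'
#' @param n_otus Number of OTUs (default 8).
#' @param totals Totals of the two samples (deep, shallow).
#' @param flagged_count Count of the long-branch OTU in the deep sample.
#' @param branch_factor Minimum long-branch to median-branch ratio.
#' @param seed Integer seed.
#' @return A list: `tree`, `table` (two samples `A`, `B`), `flagged_otu`,
#'   `depth` (the shallow total) and `p_zero` (exact probability that
#'   rarefaction of the deep sample to `depth` zeroes the flagged OTU).
#' @export
simulate_longbranch_flip <- function(n_otus = 8, totals = c(1075, 221),
                                     flagged_count = 5, branch_factor = 5,
                                     seed = 1) {
  stopifnot(n_otus >= 3, length(totals) == 2, totals[1] > totals[2],
            flagged_count >= 1)
  depth <- totals[2]
  # P(X = 0), X ~ hypergeometric: draw `depth` of `totals[1]` reads of which
  # `flagged_count` hit the flagged OTU
  p_zero <- stats::phyper(0, flagged_count, totals[1] - flagged_count, depth)
  if (p_zero <= 0.2 || p_zero >= 0.8) {
    stop(sprintf(
      "infeasible: rarefaction-to-zero probability %.3f outside (0.2, 0.8)",
      p_zero), call. = FALSE)
  }
  tree <- simulate_tree(n_otus, seed = seed, n_long_branches = 1,
                        long_branch_factor = 10 * branch_factor)
  pendant <- which(tree$edge[, 2] <= n_otus)
  long_edge <- pendant[which.max(tree$edge.length[pendant])]
  if (tree$edge.length[long_edge] <
      branch_factor * stats::median(tree$edge.length)) {
    tree$edge.length[long_edge] <- branch_factor *
      stats::median(tree$edge.length) * 1.5
  }
  flagged <- tree$tip.label[tree$edge[long_edge, 2]]
  others <- setdiff(tree$tip.label, flagged)
  withr::with_seed(as.integer(seed), {
    pa <- stats::rlnorm(length(others), 0, 1)
    a_rest <- stats::rmultinom(1, totals[1] - flagged_count,
                               pa / sum(pa))[, 1]
    pb <- stats::rlnorm(length(others), 0, 1)
    b_dom <- round(depth * 0.3)
    b_rest <- stats::rmultinom(1, depth - b_dom, pb / sum(pb))[, 1]
  })
  a <- stats::setNames(numeric(n_otus), tree$tip.label)
  b <- a
  a[others] <- a_rest
  a[flagged] <- flagged_count
  b[others] <- b_rest
  b[flagged] <- b_dom
  m <- rbind(A = a, B = b)
  list(tree = tree, table = as_count_tibble(m), flagged_otu = flagged,
       depth = depth, p_zero = p_zero)
}

#' Simulate a uniform (single-site) dataset with uneven sequencing depth
#'
#' All samples are multinomial draws from one common sparse, long-tailed
#' composition; read depths are log-uniform between `depth_range[1]` and
#' `depth_range[2]`. Any apparent structure in such data is a sampling
#' artifact, which makes this the null dataset for rarefaction-stability
#' comparisons. Defaults follow a healthy single-body-site survey: 60
#' samples, 554 OTUs, depths from 659 to 17176 reads.
#'
#' @param n_samples,n_otus Dataset size.
#' @param depth_range Minimum and maximum read depth.
#' @param tail_sd Log-normal sd of the composition (larger = sparser, more
#'   long-tailed).
#' @param n_long_branches Number of pendant branches to stretch. Long
#'   isolated branches are divergent taxa without close relatives, which in
#'   amplicon surveys are overwhelmingly *rare* taxa, so the stretched
#'   branches are drawn from OTUs in the `long_branch_band` of observed total
#'   counts — rare enough to flip in and out of rarefied tables, abundant
#'   enough to survive the usual rare-OTU filter.
#' @param long_branch_factor Branch-length stretch factor.
#' @param long_branch_band Total-count band (across all samples) from which
#'   the long-branch OTUs are drawn.
#' @param seed Integer seed.
#' @return A list: `tree`, `table` (count tibble) and `composition` (the
#'   common proportion vector).
#' @export
simulate_uniform_dataset <- function(n_samples = 60, n_otus = 554,
                                     depth_range = c(659, 17176),
                                     tail_sd = 2, n_long_branches = 25,
                                     long_branch_factor = 10,
                                     long_branch_band = c(120, 1200),
                                     seed = 1) {
  stopifnot(n_samples >= 2, depth_range[1] >= 1,
            depth_range[2] >= depth_range[1])
  tree <- simulate_tree(n_otus, seed = seed)
  withr::with_seed(as.integer(seed) + 1L, {
    p <- stats::rlnorm(n_otus, meanlog = 0, sdlog = tail_sd)
    p <- p / sum(p)
    depths <- round(exp(stats::runif(n_samples, log(depth_range[1]),
                                     log(depth_range[2]))))
    m <- t(vapply(depths, function(d) stats::rmultinom(1, d, p)[, 1],
                  numeric(n_otus)))
  })
  dimnames(m) <- list(sprintf("sample_%02d", seq_len(n_samples)),
                      tree$tip.label)
  if (n_long_branches > 0) {
    withr::with_seed(as.integer(seed) + 2L, {
      pendant <- which(tree$edge[, 2] <= n_otus)
      tot <- colSums(m)
      band <- which(tot >= long_branch_band[1] & tot <= long_branch_band[2])
      pick <- sample(band, min(n_long_branches, length(band)))
      idx <- pendant[match(pick, tree$edge[pendant, 2])]
      tree$edge.length[idx] <- tree$edge.length[idx] * long_branch_factor
    })
  }
  list(tree = tree, table = as_count_tibble(m),
       composition = stats::setNames(p, tree$tip.label))
}

#' Simulate a two-group dataset with a defined difference
#'
#' Two groups whose compositions are shifted toward disjoint clades of the
#' tree (the two children of the root), mixed with a shared baseline
#' composition: `p_g = (1 - effect_size) * base + effect_size * clade_g`.
#' With `effect_size = 0` this reduces to the uniform generator; with a
#' large effect every metric separates the groups on PC1.
#'
#' @param n_per_group Samples per group.
#' @param n_otus Number of OTUs.
#' @param effect_size Mixing weight of the group-specific clade profile, in
#'   \[0, 1\].
#' @param depth_range,tail_sd,seed As in [simulate_uniform_dataset()].
#' @return A list: `tree`, `table`, `groups` (character vector, length
#'   `2 * n_per_group`) and `composition` (per-group proportion matrix).
#' @export
simulate_two_group_dataset <- function(n_per_group = 30, n_otus = 100,
                                       effect_size = 0.5,
                                       depth_range = c(1000, 5000),
                                       tail_sd = 2, seed = 1) {
  stopifnot(effect_size >= 0, effect_size <= 1, n_per_group >= 1)
  tree <- simulate_tree(n_otus, seed = seed)
  root <- ape::Ntip(tree) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  clade1 <- if (kids[1] <= n_otus) tree$tip.label[kids[1]] else
    ape::extract.clade(tree, kids[1])$tip.label
  clade2 <- setdiff(tree$tip.label, clade1)
  withr::with_seed(as.integer(seed) + 1L, {
    base <- stats::rlnorm(n_otus, 0, tail_sd)
    base <- stats::setNames(base / sum(base), tree$tip.label)
    profile_of <- function(clade) {
      w <- stats::setNames(numeric(n_otus), tree$tip.label)
      w[clade] <- base[clade] / sum(base[clade])
      w
    }
    comp <- rbind(group1 = (1 - effect_size) * base +
                    effect_size * profile_of(clade1),
                  group2 = (1 - effect_size) * base +
                    effect_size * profile_of(clade2))
    n <- 2 * n_per_group
    depths <- round(exp(stats::runif(n, log(depth_range[1]),
                                     log(depth_range[2]))))
    groups <- rep(c("group1", "group2"), each = n_per_group)
    m <- t(vapply(seq_len(n), function(i) {
      stats::rmultinom(1, depths[i], comp[groups[i], ])[, 1]
    }, numeric(n_otus)))
  })
  dimnames(m) <- list(sprintf("%s_s%02d", groups,
                              rep(seq_len(n_per_group), 2)),
                      tree$tip.label)
  list(tree = tree, table = as_count_tibble(m), groups = groups,
       composition = comp)
}
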