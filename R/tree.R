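#' Parse a Newick tree
#'
#' Reads a phylogenetic tree from a Newick string or a file path. Leaves must
#' carry unique, non-empty OTU labels. Edges without an explicit branch length
#' are assigned length 0 with a warning (a common dialect difference between
#' tree writers); internal node labels are ignored.
#'
#' @param x A Newick string (e.g. `"((A:1,B:1):1,C:2);"`) or the path to a
#'   file containing one.
#' @return A rooted or unrooted tree of class [ape::phylo].
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' sum(tr$edge.length) # total branch length 5
#' @export
parse_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  text <- if (!grepl("[(;]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    x
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick input: ", n_open, " '(' vs ",
         n_close, " ')'", call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("no branch lengths in Newick input; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  bad <- !is.finite(tree$edge.length)
  if (any(bad)) {
    warning(sum(bad), " edge(s) without a branch length; set to 0")
    tree$edge.length[bad] <- 0
  }
  validate_tree(tree)
  tree
}

#' @keywords internal
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(tree$tip.label))) stop("empty leaf label", call. = FALSE)
  if (any(tree$edge.length < 0)) {
    stop("negative branch length(s)", call. = FALSE)
  }
  invisible(tree)
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, the
#' standard rooting for UniFrac when no outgroup is available. Total branch
#' length is conserved.
#'
#' @param tree A [ape::phylo] tree with at least two leaves and at least one
#'   positive branch length.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  validate_tree(tree)
  if (ape::Ntip(tree) < 2L) {
    stop("midpoint rooting needs at least 2 leaves", call. = FALSE)
  }
  if (all(tree$edge.length == 0)) {
    stop("midpoint undefined: all branch lengths are zero", call. = FALSE)
  }
  phangorn::midpoint(tree)
}

#' Prune a tree to a set of taxa
#'
#' Removes all leaves outside `taxa` and collapses the resulting degree-2
#' internal nodes, summing branch lengths so that path lengths among the
#' retained leaves are unchanged.
#'
#' @param tree A [ape::phylo] tree.
#' @param taxa Character vector of leaf labels to keep.
#' @return A `phylo` tree on `intersect(taxa, tree$tip.label)`.
#' @export
prune_to_taxa <- function(tree, taxa) {
  validate_tree(tree)
  keep <- intersect(tree$tip.label, taxa)
  if (!length(keep)) {
    stop("no requested taxon is a leaf of the tree", call. = FALSE)
  }
  if (length(keep) == ape::Ntip(tree)) return(tree)
  ape::keep.tip(tree, keep)
}

# Per-edge subtree sums. tip_vals is an Ntip x S matrix aligned with
# tree$tip.label; returns an E x S matrix in tree$edge row order where each
# row holds the sum of tip values in the subtree below that edge. The root
# carries no edge, so UniFrac sums over these rows are sums over all non-root
# edges.
edge_subtree_sums <- function(tree, tip_vals) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  s <- ncol(tip_vals)
  vals <- matrix(0, n_node, s)
  vals[seq_len(n_tip), ] <- tip_vals
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    vals[po[k, 1L], ] <- vals[po[k, 1L], ] + vals[po[k, 2L], ]
  }
  vals[tree$edge[, 2L], , drop = FALSE]
}

# Proportion matrix (samples x OTUs, possibly a subset of leaves) -> tip value
# matrix (Ntip x S) with zeros for leaves absent from the table.
tip_value_matrix <- function(tree, p_mat) {
  n_tip <- ape::Ntip(tree)
  out <- matrix(0, n_tip, nrow(p_mat))
  idx <- match(colnames(p_mat), tree$tip.label)
  if (anyNA(idx)) {
    stop("OTU(s) absent from the tree: ",
         paste(colnames(p_mat)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out[idx, ] <- t(p_mat)
  out
}

# E x S matrix of per-branch masses for a samples x OTUs proportion matrix.
branch_mass_matrix <- function(tree, p_mat) {
  edge_subtree_sums(tree, tip_value_matrix(tree, p_mat))
}

#' Propagate sample abundances onto tree branches
#'
#' For each branch of the tree and each sample, computes the branch mass: the
#' sum of proportional abundances of all leaf OTUs in the subtree below that
#' branch. A branch "belongs" to a sample when its mass is positive. Branch
#' masses are the quantities every UniFrac weighting is computed from.
#'
#' @param tree A [ape::phylo] tree whose leaves cover all OTUs with non-zero
#'   abundance.
#' @param proportions A named numeric vector of per-OTU proportions for one
#'   sample (summing to 1, or all zero), or a samples-by-OTUs matrix /
#'   count-table tibble of proportions with one row per sample.
#' @return A tibble with one row per branch: `parent` and `child` node ids
#'   (in `tree$edge` order), `branch_length`, and one mass column per sample
#'   (named `mass` for a single unnamed vector input).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' branch_mass(tr, c(A = 0.2, B = 0.3, C = 0.5))
#' @export
branch_mass <- function(tree, proportions) {
  validate_tree(tree)
  if (is.null(dim(proportions))) {
    if (is.null(names(proportions))) {
      stop("proportions must be named by OTU", call. = FALSE)
    }
    p_mat <- matrix(proportions, nrow = 1,
                    dimnames = list("mass", names(proportions)))
  } else {
    p_mat <- as_sample_matrix(proportions, integer_counts = FALSE)
  }
  tot <- rowSums(p_mat)
  off <- abs(tot - 1) > 1e-8 & tot != 0
  if (any(off)) {
    stop("proportions must sum to 1 (or all be zero); offending sample(s): ",
         paste(rownames(p_mat)[off], collapse = ", "), call. = FALSE)
  }
  m <- branch_mass_matrix(tree, p_mat)
  colnames(m) <- rownames(p_mat)
  tibble::tibble(
    parent = tree$edge[, 1L],
    child = tree$edge[, 2L],
    branch_length = tree$edge.length,
    tibble::as_tibble(m)
  )
}

#' One-line summary of a tree
#'
#' @param tree A [ape::phylo] tree.
#' @return Invisibly, a list with `n_leaves`, `total_length` and `max_depth`
#'   (largest root-to-leaf path length); printed as a single line.
#' @export
tree_summary <- function(tree) {
  validate_tree(tree)
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  out <- list(n_leaves = ape::Ntip(tree),
              total_length = sum(tree$edge.length),
              max_depth = max(depths))
  cat(sprintf("tree: %d leaves, total branch length %.6g, max depth %.6g\n",
              out$n_leaves, out$total_length, out$max_depth))
  invisible(out)
}
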