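#' Principal coordinates analysis
#'
#' Classical metric scaling of a symmetric, zero-diagonal dissimilarity
#' matrix: double-centering of `-D^2 / 2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; axes with non-positive eigenvalues are dropped but their
#' eigenvalues are reported, since a negative eigenvalue is the signature of
#' a non-Euclidean (triangle-inequality-violating) input. Variance explained
#' is the eigenvalue over the sum of positive eigenvalues, with no Lingoes or
#' Cailliez correction. For determinism each axis is flipped so that the
#' coordinate with the largest magnitude is positive.
#'
#' @param d A `uf_dist`, [stats::dist] or square symmetric matrix.
#' @return A `uf_ordination`: `points` (samples x axes), `eigenvalues` (all,
#'   descending), `proportion_explained` (per retained axis),
#'   `n_negative_eigenvalues`, `sample_ids`, `metric`.
#' @export
pcoa <- function(d) {
  metric <- if (inherits(d, "uf_dist")) d$metric else "unknown"
  m <- if (inherits(d, "uf_dist")) d$matrix else as.matrix(d)
  if (nrow(m) != ncol(m) ||
      !isTRUE(all.equal(m, t(m), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    stop("pcoa() needs a symmetric square matrix", call. = FALSE)
  }
  if (any(abs(diag(m)) > 1e-12)) {
    stop("pcoa() needs a zero diagonal", call. = FALSE)
  }
  n <- nrow(m)
  ids <- rownames(m) %||% paste0("S", seq_len(n))
  cs <- suppressWarnings(
    stats::cmdscale(m, k = max(n - 1, 1), eig = TRUE, add = FALSE))
  eig <- sort(cs$eig, decreasing = TRUE)      # all n, incl. negatives
  tol <- if (max(abs(eig)) > 0) max(abs(eig)) * 1e-10 else 0
  n_neg <- sum(eig < -tol)
  pts <- cs$points                            # positive-eigenvalue axes only
  if (is.null(dim(pts)) || ncol(pts) == 0) {
    pts <- matrix(0, n, 2, dimnames = list(ids, c("PC1", "PC2")))
    return(new_uf_ordination(pts, eig, rep(0, 2), n_neg, ids, metric))
  }
  # deterministic axis orientation
  for (k in seq_len(ncol(pts))) {
    imax <- which.max(abs(pts[, k]))
    if (pts[imax, k] < 0) pts[, k] <- -pts[, k]
  }
  dimnames(pts) <- list(ids, paste0("PC", seq_len(ncol(pts))))
  eig_pos <- eig[seq_len(ncol(pts))]
  prop <- eig_pos / sum(eig[eig > tol])
  new_uf_ordination(pts, eig, prop, n_neg, ids, metric)
}

new_uf_ordination <- function(points, eig, prop, n_neg, ids, metric) {
  structure(list(points = points, eigenvalues = eig,
                 proportion_explained = prop,
                 n_negative_eigenvalues = n_neg,
                 sample_ids = ids, metric = metric),
            class = "uf_ordination")
}

#' @export
print.uf_ordination <- function(x, ...) {
  cat(sprintf(
    "PCoA of %d samples (%s): %d axes retained, %d negative eigenvalue(s)\n",
    length(x$sample_ids), x$metric, ncol(x$points),
    x$n_negative_eigenvalues))
  if (length(x$proportion_explained)) {
    cat("variance explained:",
        paste0(sprintf("%.1f%%", 100 * utils::head(x$proportion_explained, 4)),
               collapse = ", "),
        if (length(x$proportion_explained) > 4) "..." else "", "\n")
  }
  invisible(x)
}

#' @describeIn pcoa Coordinates as a tibble (`sample_id`, `PC1`, `PC2`, ...).
#' @param x,object A `uf_ordination`.
#' @param ... Unused.
#' @method tidy uf_ordination
#' @export
tidy.uf_ordination <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_ids,
                 tibble::as_tibble(x$points))
}

#' @describeIn pcoa One-row summary (axes retained, PC1/PC2 variance,
#'   negative eigenvalues).
#' @method glance uf_ordination
#' @export
glance.uf_ordination <- function(x, ...) {
  pe <- x$proportion_explained
  tibble::tibble(n_samples = length(x$sample_ids),
                 n_axes = ncol(x$points),
                 prop_pc1 = if (length(pe)) pe[1] else NA_real_,
                 prop_pc2 = if (length(pe) > 1) pe[2] else NA_real_,
                 n_negative_eigenvalues = x$n_negative_eigenvalues,
                 metric = x$metric)
}

#' @describeIn pcoa PC1 vs PC2 scatter with percent variance in the axis
#'   labels.
#' @param colour Optional vector (length = samples) mapped to point colour.
#' @method autoplot uf_ordination
#' @export
autoplot.uf_ordination <- function(object, colour = NULL, ...) {
  df <- tidy(object)
  if (ncol(object$points) < 2) df$PC2 <- 0
  pe <- object$proportion_explained
  lab <- function(i) {
    sprintf("PC%d (%.1f%%)", i, if (length(pe) >= i) 100 * pe[i] else 0)
  }
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(x = lab(1), y = lab(2), title = object$metric) +
    ggplot2::theme_bw()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
}

#' Write an ordination as TSV
#'
#' Leading `#`-prefixed lines carry the eigenvalues and the proportion of
#' variance explained per retained axis; the body holds one coordinate row
#' per sample.
#'
#' @param ordination A `uf_ordination`.
#' @param path Output path.
#' @export
write_ordination <- function(ordination, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# eigenvalues\t",
                    paste(format(ordination$eigenvalues, digits = 10),
                          collapse = "\t")), con)
  writeLines(paste0("# proportion_explained\t",
                    paste(format(ordination$proportion_explained, digits = 10),
                          collapse = "\t")), con)
  df <- as.data.frame(tidy(ordination))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Procrustes overlay of one ordination onto another
#'
#' Translates, orthogonally rotates (reflections allowed) and, by default,
#' isotropically scales the target configuration to minimize the sum of
#' squared differences to the reference — the adjustment used to overlay the
#' PCoA of one rarefaction instance onto a reference instance. Solved through
#' [vegan::procrustes()].
#'
#' @param target,reference `uf_ordination` objects or coordinate matrices
#'   with matching samples in matching order.
#' @param n_axes Number of leading axes to align (default 2, the plotted
#'   plane). Configurations with fewer axes are zero-padded.
#' @param scale Allow isotropic scaling (default `TRUE`).
#' @return A `uf_procrustes`: `coordinates` (aligned target), `rotation`,
#'   `scale`, `translation` and `disparity` (residual sum of squares over the
#'   centred reference sum of squares; 0 means exact overlay).
#' @export
procrustes_align <- function(target, reference, n_axes = 2, scale = TRUE) {
  xt <- ordination_coords(target, n_axes)
  xr <- ordination_coords(reference, n_axes)
  if (nrow(xt) != nrow(xr) ||
      (!is.null(rownames(xt)) && !is.null(rownames(xr)) &&
       !identical(rownames(xt), rownames(xr)))) {
    stop("target and reference must hold the same samples in the same order",
         call. = FALSE)
  }
  pr <- vegan::procrustes(X = xr, Y = xt, scale = scale, symmetric = FALSE)
  # full affine map y -> scale * y %*% rotation + translation, applied to the
  # original (uncentered) target, lands in the reference frame
  aligned <- sweep(pr$scale * (xt %*% pr$rotation), 2,
                   as.numeric(pr$translation), "+")
  dimnames(aligned) <- dimnames(xr)
  ss_ref <- sum(sweep(xr, 2, colMeans(xr))^2)
  disparity <- if (ss_ref > 0) sum((xr - aligned)^2) / ss_ref else 0
  structure(list(coordinates = aligned, rotation = pr$rotation,
                 scale = pr$scale, translation = pr$translation,
                 disparity = disparity),
            class = "uf_procrustes")
}

ordination_coords <- function(x, n_axes) {
  m <- if (inherits(x, "uf_ordination")) x$points else as.matrix(x)
  if (ncol(m) < n_axes) {
    pad <- matrix(0, nrow(m), n_axes - ncol(m))
    m <- cbind(m, pad)
  }
  m[, seq_len(n_axes), drop = FALSE]
}

#' @export
print.uf_procrustes <- function(x, ...) {
  cat(sprintf("Procrustes overlay: %d samples, %d axes, disparity %.3g\n",
              nrow(x$coordinates), ncol(x$coordinates), x$disparity))
  invisible(x)
}
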