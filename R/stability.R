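#' Per-sample relative PC1 deviation between two rarefaction instances
#'
#' `|V1 - Vi| / range(V1, Vi)`, where `V1` is the reference first principal
#' coordinate, `Vi` the (Procrustes-aligned) first principal coordinate of a
#' subsequent rarefaction, and the range is the max minus min of the pooled
#' values of both vectors — one scalar per pair, so the deviations of all
#' samples share a denominator and are comparable. Scale-invariant: rescaling
#' both vectors by the same positive constant leaves the result unchanged.
#'
#' @param v1,vi Numeric vectors of equal length, same sample order.
#' @return Non-negative per-sample deviations.
#' @export
relative_deviation <- function(v1, vi) {
  if (length(v1) != length(vi)) {
    stop("v1 and vi must have equal length", call. = FALSE)
  }
  pooled <- range(c(v1, vi))
  rng <- diff(pooled)
  if (rng <= 0) {
    stop("degenerate ordination: pooled PC1 range is zero", call. = FALSE)
  }
  abs(v1 - vi) / rng
}

#' Rarefaction-instance stability of dissimilarity metrics
#'
#' Quantifies how much a metric's ordination depends on the random draw used
#' for rarefaction. The table is rarefied `n_rarefactions` times (seeds
#' `seed + i` for auditability); every rarefied table feeds every requested
#' metric; each resulting distance matrix is ordinated by PCoA and overlaid
#' onto the first rarefaction's ordination by Procrustes (first `n_axes`
#' axes); the per-sample relative PC1 deviation is summarized per rarefaction
#' by its maximum and median. Samples whose aligned PC1 changes sign between
#' rarefactions 1 and 2 are reported as migrations — samples that would have
#' switched clusters had the experiment been run once.
#'
#' @param table Count table (tibble or samples x OTUs matrix).
#' @param tree Rooted [ape::phylo] tree (not needed if only `"braycurtis"`).
#' @param metrics Metrics to assess (default: all five).
#' @param n_rarefactions Number of rarefaction instances (>= 2).
#' @param depth Rarefaction depth (default: minimum sample total).
#' @param seed Base seed; instance `i` uses `seed + i`.
#' @param n_axes Axes used for the Procrustes overlay (default 2, matching
#'   overlaid 2-D PCoA plots).
#' @return A `uf_stability` object: `summary` (tibble: metric, rarefaction,
#'   max_vres, median_vres), `vres` (per-metric matrices, rarefactions x
#'   samples), `migrations` (per-metric character vectors), plus the run
#'   settings. Use `tidy()`, `glance()` or `autoplot()`.
#' @export
rarefaction_stability <- function(table, tree = NULL, metrics = UF_METRICS,
                                  n_rarefactions = 100, depth = NULL,
                                  seed = 1, n_axes = 2) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  stopifnot(n_rarefactions >= 2)
  m <- as_sample_matrix(table)
  if (!is.null(tree)) {
    # one-time reconciliation: the experiment's tree is the table's tree.
    # V_res is range-normalized, so the branch-length normalizer convention
    # cannot affect it, and ratio UniFrac needs every leaf covered.
    tree <- prune_to_taxa(tree, colnames(m))
    m <- m[, intersect(colnames(m), tree$tip.label), drop = FALSE]
  }
  if (is.null(depth)) depth <- min(rowSums(m))
  tables <- lapply(seq_len(n_rarefactions), function(i) {
    as_sample_matrix(rarefy(m, depth = depth, seed = seed + i))
  })
  vres <- migrations <- list()
  rows <- list()
  for (metric in metrics) {
    ords <- lapply(tables, function(tb) {
      pcoa(distance_matrix(tb, tree, metric, rarefy_first = FALSE))
    })
    ref <- ordination_coords(ords[[1]], n_axes)
    v1 <- ref[, 1]
    vmat <- matrix(0, n_rarefactions, nrow(m),
                   dimnames = list(NULL, rownames(m)))
    flipped <- character()
    for (i in seq_len(n_rarefactions)[-1]) {
      aligned <- procrustes_align(ords[[i]], ords[[1]],
                                  n_axes = n_axes)$coordinates
      vi <- aligned[, 1]
      vmat[i, ] <- relative_deviation(v1, vi)
      if (i == 2) flipped <- rownames(m)[sign(v1) * sign(vi) < 0]
    }
    vres[[metric]] <- vmat
    migrations[[metric]] <- flipped
    rows[[metric]] <- tibble::tibble(
      metric = metric, rarefaction = seq_len(n_rarefactions),
      max_vres = apply(vmat, 1, max), median_vres = apply(vmat, 1, median))
  }
  structure(list(summary = dplyr::bind_rows(rows), vres = vres,
                 migrations = migrations, metrics = metrics,
                 n_rarefactions = n_rarefactions, depth = depth, seed = seed,
                 n_axes = n_axes),
            class = "uf_stability")
}

#' @export
print.uf_stability <- function(x, ...) {
  cat(sprintf("rarefaction stability: %d instances at depth %d\n",
              x$n_rarefactions, as.integer(x$depth)))
  print(glance(x))
  invisible(x)
}

#' @describeIn rarefaction_stability Per-rarefaction summary tibble.
#' @param x,object A `uf_stability`.
#' @param ... Unused.
#' @method tidy uf_stability
#' @export
tidy.uf_stability <- function(x, ...) x$summary

#' @describeIn rarefaction_stability One row per metric: mean max/median
#'   deviation and number of PC1 sign-flip migrations.
#' @method glance uf_stability
#' @export
glance.uf_stability <- function(x, ...) {
  out <- dplyr::summarise(dplyr::group_by(x$summary, .data$metric),
                          mean_max_vres = mean(.data$max_vres),
                          mean_median_vres = mean(.data$median_vres),
                          .groups = "drop")
  out$n_migrations <- lengths(x$migrations)[out$metric]
  out
}

#' @describeIn rarefaction_stability Max-vs-median deviation scatter with a
#'   95\% confidence ellipse per metric.
#' @param level Ellipse confidence level.
#' @method autoplot uf_stability
#' @export
autoplot.uf_stability <- function(object, level = 0.95, ...) {
  df <- object$summary[object$summary$rarefaction > 1, ]
  paths <- dplyr::bind_rows(lapply(split(df, df$metric), function(d) {
    e <- summarize_ellipse(cbind(d$median_vres, d$max_vres), level = level)
    if (e$degenerate) return(NULL)
    p <- ellipse_points(e)
    tibble::tibble(metric = d$metric[1], median_vres = p[, 1],
                   max_vres = p[, 2])
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$median_vres, .data$max_vres,
                                        colour = .data$metric)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "median relative deviation",
                  y = "maximum relative deviation") +
    ggplot2::theme_bw()
  if (nrow(paths)) {
    p <- p + ggplot2::geom_path(data = paths, linewidth = 0.8)
  }
  p
}

#' Bivariate-normal confidence ellipse of a point cloud
#'
#' Fits the sample mean and covariance of a 2-D cloud and returns the ellipse
#' containing the requested probability mass under a bivariate normal: axes
#' are the covariance eigenvectors, half-axis lengths are
#' `sqrt(eigenvalue * qchisq(level, df = 2))`.
#'
#' @param points A two-column matrix or data frame (e.g. median vs max
#'   deviation per rarefaction).
#' @param level Confidence level (default 0.95).
#' @return A `uf_ellipse` list: `center`, `radii` (half-axis lengths,
#'   descending), `angle` (radians, first axis vs x), `cov`, `level`,
#'   `degenerate` (singular covariance: the cloud is essentially a point or a
#'   line).
#' @export
summarize_ellipse <- function(points, level = 0.95) {
  m <- as.matrix(points)
  if (ncol(m) != 2 || nrow(m) < 3) {
    stop("need >= 3 points with 2 columns", call. = FALSE)
  }
  ctr <- colMeans(m)
  s <- stats::cov(m)
  e <- eigen(s, symmetric = TRUE)
  scale2 <- stats::qchisq(level, df = 2)
  radii <- sqrt(pmax(e$values, 0) * scale2)
  tr <- sum(diag(s))
  degenerate <- tr <= 0 || min(e$values) <= 1e-12 * max(tr, 1)
  structure(list(center = ctr, radii = radii,
                 angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                 cov = s, level = level, degenerate = degenerate),
            class = "uf_ellipse")
}

#' @rdname summarize_ellipse
#' @param ellipse A `uf_ellipse`.
#' @param n Number of boundary points to return.
#' @return `ellipse_points()`: an `n` x 2 matrix tracing the boundary.
#' @export
ellipse_points <- function(ellipse, n = 181) {
  th <- seq(0, 2 * pi, length.out = n)
  circ <- cbind(ellipse$radii[1] * cos(th), ellipse$radii[2] * sin(th))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  sweep(circ %*% t(rot), 2, ellipse$center, "+")
}

#' @rdname summarize_ellipse
#' @return `in_ellipse()`: logical vector, whether each point falls inside.
#' @export
in_ellipse <- function(points, ellipse) {
  m <- sweep(as.matrix(points), 2, ellipse$center)
  rot <- matrix(c(cos(-ellipse$angle), sin(-ellipse$angle),
                  -sin(-ellipse$angle), cos(-ellipse$angle)), 2, 2)
  u <- m %*% t(rot)
  (u[, 1] / ellipse$radii[1])^2 + (u[, 2] / ellipse$radii[2])^2 <= 1
}

#' Write a stability report as TSV
#'
#' @param stability A `uf_stability`.
#' @param path Report path (per-rarefaction max/median deviation); the
#'   migration list goes to `paste0(path, ".migrations.tsv")`.
#' @export
write_stability_report <- function(stability, path) {
  utils::write.table(as.data.frame(stability$summary), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mig <- dplyr::bind_rows(lapply(names(stability$migrations), function(mt) {
    s <- stability$migrations[[mt]]
    if (!length(s)) return(NULL)
    tibble::tibble(metric = mt, sample_id = s)
  }))
  if (!nrow(mig)) mig <- tibble::tibble(metric = character(),
                                        sample_id = character())
  utils::write.table(as.data.frame(mig), paste0(path, ".migrations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
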