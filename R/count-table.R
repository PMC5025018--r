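# Canonical in-memory form used throughout: a base matrix, samples in rows,
# OTUs in columns, with dimnames. User-facing functions accept and return
# tibbles whose first column is `sample_id`.

#' @keywords internal
as_sample_matrix <- function(table, integer_counts = TRUE) {
  if (is.matrix(table)) {
    m <- table
    if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  } else if (is.data.frame(table)) {
    df <- as.data.frame(table)
    id_col <- which(vapply(df, is.character, logical(1)))[1]
    if (is.na(id_col)) {
      m <- as.matrix(df)
      rownames(m) <- paste0("S", seq_len(nrow(m)))
    } else {
      m <- as.matrix(df[, -id_col, drop = FALSE])
      rownames(m) <- df[[id_col]]
    }
  } else {
    stop("expected a count-table tibble or a samples x OTUs matrix",
         call. = FALSE)
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing values in count table", call. = FALSE)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at sample '%s', OTU '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
  }
  if (integer_counts && any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at sample '%s', OTU '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate OTU ids", call. = FALSE)
  m
}

#' @keywords internal
as_count_tibble <- function(m) {
  tibble::tibble(sample_id = rownames(m), tibble::as_tibble(m))
}

#' Read an OTU count table
#'
#' Reads a tab-separated count table in either orientation. The classic QIIME
#' layout (`#OTU ID` header, OTU rows, sample columns) is auto-detected from
#' the first header token and transposed; a header starting with `sample` is
#' read as sample rows directly. A path ending in `.biom` is read through the
#' biomformat package when it is installed.
#'
#' @param path Path to a TSV (or JSON BIOM) count table.
#' @return A tibble with a `sample_id` column and one non-negative integer
#'   column per OTU.
#' @export
read_count_table <- function(path) {
  if (grepl("\\.biom$", path)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading .biom needs the 'biomformat' package", call. = FALSE)
    }
    m <- t(as.matrix(biomformat::biom_data(biomformat::read_biom(path))))
    return(as_count_tibble(as_sample_matrix(m)))
  }
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  if (!nrow(df) || ncol(df) < 2L) stop("empty count table", call. = FALSE)
  first <- names(df)[1]
  if (grepl("otu", first, ignore.case = TRUE)) {
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(m) <- df[[1]]
  } else if (grepl("sample", first, ignore.case = TRUE)) {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  } else {
    stop("cannot detect table orientation: first header field '", first,
         "' names neither OTUs nor samples", call. = FALSE)
  }
  as_count_tibble(as_sample_matrix(m))
}

#' Write an OTU count table
#'
#' @param table Count table (tibble or samples x OTUs matrix).
#' @param path Output TSV path.
#' @param orientation `"otu"` (default) writes the classic QIIME layout
#'   (`#OTU ID` rows by sample columns); `"sample"` writes sample rows.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, orientation = c("otu", "sample")) {
  orientation <- match.arg(orientation)
  m <- as_sample_matrix(table)
  if (orientation == "otu") {
    df <- data.frame(`#OTU ID` = colnames(m), t(m), check.names = FALSE)
  } else {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove rare OTUs
#'
#' Drops OTUs whose total count across all samples is below `min_total`
#' (default 100, the usual pre-filter before rarefaction-based analyses).
#'
#' @param table Count table (tibble or matrix).
#' @param min_total Minimum total count an OTU must reach to be retained.
#' @return Filtered count table tibble; sample order unchanged.
#' @export
filter_rare_otus <- function(table, min_total = 100) {
  stopifnot(min_total >= 0)
  m <- as_sample_matrix(table)
  keep <- colSums(m) >= min_total
  if (!any(keep)) {
    stop("all OTUs removed at min_total = ", min_total, call. = FALSE)
  }
  as_count_tibble(m[, keep, drop = FALSE])
}

#' Rarefy a count table
#'
#' Subsamples every sample, without replacement, to a common sequencing depth
#' (a multivariate hypergeometric draw per sample). Samples are processed in
#' label-sorted order from a single seeded generator, so the same
#' `seed` always yields the same table regardless of input row order.
#'
#' @param table Count table (tibble or matrix).
#' @param depth Target depth; defaults to the minimum sample total.
#' @param seed Integer seed (required: rarefaction is a random point estimate
#'   and must be reproducible).
#' @return Rarefied count table tibble, every sample totalling `depth`,
#'   original sample order.
#' @export
rarefy <- function(table, depth = NULL, seed) {
  if (missing(seed)) stop("rarefy() requires a seed", call. = FALSE)
  m <- as_sample_matrix(table)
  totals <- rowSums(m)
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  if (any(totals < depth)) {
    stop("depth ", depth, " exceeds total of sample(s): ",
         paste(rownames(m)[totals < depth], collapse = ", "), call. = FALSE)
  }
  out <- m
  withr::with_seed(as.integer(seed), {
    for (s in sort(rownames(m))) {
      x <- m[s, ]
      if (sum(x) == depth) next
      drawn <- sample.int(sum(x), depth)
      out[s, ] <- tabulate(findInterval(drawn - 1L, cumsum(x)) + 1L,
                           nbins = ncol(m))
    }
  })
  as_count_tibble(out)
}

#' Convert counts to proportions
#'
#' @param table Count table (tibble or matrix); every sample total must be
#'   positive.
#' @return Tibble of per-sample proportional abundances (rows sum to 1).
#' @export
to_proportions <- function(table) {
  m <- as_sample_matrix(table)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("zero-total sample(s): ",
         paste(rownames(m)[totals == 0], collapse = ", "), call. = FALSE)
  }
  as_count_tibble(m / totals)
}

#' Replace zero counts with small positive proportions
#'
#' Whether a low-abundance OTU shows up as a zero or a small positive count is
#' a sampling artifact, and log-ratio quantities (the ratio UniFrac weighting)
#' are undefined at zero. This applies a Bayesian-multiplicative replacement:
#' each zero cell receives a prior pseudocount (`pseudo`, default 0.5) on the
#' count scale, positives are adjusted multiplicatively, and each sample is
#' re-closed to sum to 1. Ratios among originally positive parts are
#' preserved, and every replaced value is strictly below the smallest observed
#' non-zero proportion in its sample.
#'
#' @param table Count table (tibble or matrix), at least one positive count
#'   per sample.
#' @param method Only `"bayesian"` is implemented.
#' @param pseudo Prior pseudocount per zero cell.
#' @return Tibble of strictly positive proportions (rows sum to 1).
#' @export
replace_zeros <- function(table, method = "bayesian", pseudo = 0.5) {
  method <- match.arg(method, "bayesian")
  stopifnot(pseudo > 0)
  m <- as_sample_matrix(table)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(rownames(m)[totals == 0], collapse = ", "), call. = FALSE)
  }
  z <- rowSums(m == 0)
  denom <- totals + pseudo * z
  p <- m / denom
  p[m == 0] <- (pseudo / denom)[row(m)[m == 0]]
  as_count_tibble(p)
}
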