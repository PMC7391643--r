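# Hierarchical clustering of TPM profiles: Pearson correlation distance
# with complete linkage, as used for tissue-expression heatmaps.

#' Pearson correlation distance between gene expression profiles
#'
#' `d(i, j) = 1 - r(i, j)` over (optionally row-scaled) profiles.
#' Row scaling centers each gene and scales it to unit variance (the
#' heatmap convention); zero-variance rows are dropped with a warning,
#' since their correlation is undefined.
#'
#' @param m Numeric matrix, genes x samples (>= 2 columns).
#' @param scaled Center/scale rows before correlating (default `TRUE`).
#' @return Symmetric distance matrix with zero diagonal, entries in
#'   \[0, 2\].
#' @export
correlationDistance <- function(m, scaled = TRUE) {
  if (ncol(m) < 2L) stop("need >= 2 columns to correlate profiles")
  v <- apply(m, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance row(s) dropped")
    m <- m[v > 0, , drop = FALSE]
  }
  if (scaled) m <- t(scale(t(m)))
  d <- 1 - stats::cor(t(m))
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering of a distance matrix with complete linkage
#' (merge heights are non-decreasing), optionally cut into `k` flat
#' clusters.
#'
#' @param d Distance matrix (square symmetric matrix or `dist`).
#' @param k Optional number of flat clusters.
#' @return List: `tree` (an `hclust`) and `labels` (named integer vector,
#'   `NULL` when `k` is missing).
#' @export
clusterComplete <- function(d, k = NULL) {
  dd <- if (inherits(d, "dist")) d else stats::as.dist(d)
  n <- attr(dd, "Size")
  if (!is.null(k) && k > n) stop("k exceeds the number of items")
  tree <- stats::hclust(dd, method = "complete")
  labels <- if (!is.null(k)) stats::cutree(tree, k = k) else NULL
  list(tree = tree, labels = labels)
}

#' Average replicate columns per tissue
#'
#' @param m Genes x samples matrix.
#' @param tissues Character vector assigning each column to a tissue.
#' @return Genes x tissues matrix of mean TPM.
#' @export
averageByTissue <- function(m, tissues) {
  stopifnot(length(tissues) == ncol(m))
  out <- sapply(unique(tissues), function(tt)
    rowMeans(m[, tissues == tt, drop = FALSE]))
  out
}
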