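# Cysteine-anchored alignment of cyclotide domains, p-distances,
# neighbor-joining trees and bootstrap supports.

#' Cysteine-anchored alignment of cyclotide domains
#'
#' Exploits the conserved six-cysteine framework: the sequence blocks of
#' each domain (N-terminal flank, loops 1-5, post-Cys-VI tail) are padded
#' right with gaps to the per-block maximum length, so the six cysteine
#' columns are gap-free and aligned. Domains without exactly six
#' cysteines are excluded with a warning.
#'
#' @param domains List of [CyclotideDomain-class] objects.
#' @return `AAStringSet` of equal-length gapped rows; ungapping a row
#'   recovers the mature sequence.
#' @export
cysAnchorAlign <- function(domains) {
  six <- vapply(domains, function(d) length(d@cysPositions) == 6L,
                logical(1))
  if (any(!six))
    warning(sum(!six), " domain(s) without a 6-Cys framework excluded")
  domains <- domains[six]
  if (!length(domains)) stop("no 6-cysteine domains to align")
  blocks <- lapply(domains, function(d) {
    cp <- d@cysPositions
    m <- d@mature
    c(pre = substr(m, 1L, cp[1L] - 1L),
      vapply(1:5, function(i) substr(m, cp[i] + 1L, cp[i + 1L] - 1L),
             character(1)),
      post = substr(m, cp[6L] + 1L, nchar(m)))
  })
  bmat <- do.call(rbind, blocks)
  widths <- apply(nchar(bmat), 2L, max)
  rows <- apply(bmat, 1L, function(b) {
    padded <- vapply(seq_along(b), function(j)
      paste0(b[j], strrep("-", widths[j] - nchar(b[j]))), character(1))
    paste0(padded[1L], "C", padded[2L], "C", padded[3L], "C", padded[4L],
           "C", padded[5L], "C", padded[6L], "C", padded[7L])
  })
  out <- Biostrings::AAStringSet(rows)
  names(out) <- vapply(domains, function(d) d@id, character(1))
  out
}

#' p-distance matrix from an alignment
#'
#' `d(i, j)` = mismatches / compared columns, comparing only columns where
#' neither row has a gap (pairwise deletion). Identical rows give 0; rows
#' differing at every compared column give 1.
#'
#' @param a `AAStringSet` of equal-length gapped rows (or character
#'   vector).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pDistance <- function(a) {
  rows <- stats::setNames(as.character(a), names(a))
  if (length(unique(nchar(rows))) != 1L) stop("rows differ in length")
  mat <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    d[i, j] <- d[j, i] <- if (any(ok))
      mean(mat[i, ok] != mat[j, ok]) else 0
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei NJ on a distance matrix; negative branch lengths are clamped
#' to zero. Requires at least three taxa.
#'
#' @param d Symmetric distance matrix with row/column names.
#' @return An `ape` `phylo` tree (unrooted).
#' @export
njTree <- function(d) {
  if (nrow(d) < 3L) stop("NJ needs >= 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap supports for an NJ tree
#'
#' Builds the point-estimate NJ tree from the full alignment, then
#' resamples alignment columns with replacement `nReps` times, rebuilds
#' the tree for each replicate, and reports for each internal edge of the
#' point tree the percentage of replicates containing the same
#' bipartition. Deterministic given `seed`.
#'
#' @param a Gapped alignment (`AAStringSet` or character vector).
#' @param nReps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed (mandatory).
#' @return The point-estimate `phylo` tree with node labels set to
#'   integer percent supports.
#' @export
bootstrapTree <- function(a, nReps = 1000L, seed) {
  rows <- stats::setNames(as.character(a), names(a))
  if (length(rows) < 3L) stop("need >= 3 sequences")
  mat <- do.call(rbind, strsplit(rows, ""))
  rownames(mat) <- names(rows)
  point <- njTree(pDistance(rows))
  ncols <- ncol(mat)
  trees <- withSeed(seed, lapply(seq_len(nReps), function(r) {
    idx <- sample.int(ncols, ncols, replace = TRUE)
    sub <- apply(mat[, idx, drop = FALSE], 1L, paste, collapse = "")
    njTree(pDistance(sub))
  }))
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(point, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  point$node.label <- round(100 * counts / nReps)
  point
}

#' Write a tree in Newick format
#'
#' Bootstrap supports, when present, are written as internal node labels.
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTreeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
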