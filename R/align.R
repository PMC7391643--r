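# Pairwise alignment wrappers (BLOSUM62, affine gaps) and site maps.
#
# Scoring convention: a gap run of length L costs gapOpen + L * gapExtend
# (BLAST-style; defaults 11/1).

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

alignStats <- function(pa, qlen) {
  qa <- chars(as.character(Biostrings::alignedPattern(pa)[[1L]]))
  ta <- chars(as.character(Biostrings::alignedSubject(pa)[[1L]]))
  cols <- length(qa)
  matches <- sum(qa == ta & qa != "-")
  qres <- sum(qa != "-")
  list(identity = if (cols) 100 * matches / cols else 0,
       coverage = 100 * qres / qlen,
       columns = cols, matches = matches)
}

#' Optimal local (Smith-Waterman) alignment
#'
#' Affine-gap local alignment of two protein sequences under a substitution
#' matrix (default BLOSUM62). Percent identity is computed over aligned
#' columns including gaps; coverage is the fraction of the query aligned.
#'
#' @param q,t Query and target protein sequences (strings or `AAString`).
#' @param matrix Substitution matrix (default BLOSUM62).
#' @param gapOpen,gapExtend Affine gap penalties (positive costs).
#' @return A list of class `"alignmentHit"`: `query`, `target` (ids when the
#'   inputs are named), `score`, `identity`, `coverage`, and 0-based
#'   half-open aligned coordinates `qstart`, `qend`, `tstart`, `tend`. An
#'   all-negative pair yields `score = 0` with an empty alignment.
#' @export
localAlign <- function(q, t, matrix = blosum62, gapOpen = 11, gapExtend = 1) {
  qs <- as.character(q)
  ts <- as.character(t)
  if (!nzchar(qs) || !nzchar(ts)) stop("sequences must be non-empty")
  checkProtein(qs, "query")
  checkProtein(ts, "target")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qs), Biostrings::AAString(ts),
    substitutionMatrix = matrix, gapOpening = gapOpen,
    gapExtension = gapExtend, type = "local")
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(structure(list(query = names(q), target = names(t), score = 0,
                          identity = 0, coverage = 0, qstart = 0L,
                          qend = 0L, tstart = 0L, tend = 0L),
                     class = "alignmentHit"))
  }
  st <- alignStats(pa, nchar(qs))
  structure(list(
    query = names(q), target = names(t), score = sc,
    identity = st$identity, coverage = st$coverage,
    qstart = pa@pattern@range@start - 1L,
    qend = pa@pattern@range@start - 1L + pa@pattern@range@width,
    tstart = pa@subject@range@start - 1L,
    tend = pa@subject@range@start - 1L + pa@subject@range@width),
    class = "alignmentHit")
}

#' Optimal global (Needleman-Wunsch) alignment with a site map
#'
#' Affine-gap global alignment, returning the aligned rows and a site map:
#' for every target (reference) position aligned to a query residue, the
#' 1-based query position. The map is strictly increasing over mapped
#' positions; unmapped (gapped) positions are `NA`. Used to transfer
#' functionally important residue annotations from a reference.
#'
#' @inheritParams localAlign
#' @return A list of class `"globalAlignment"`: `score`, `identity`,
#'   `qaln`, `taln` (gapped rows) and `siteMap` (integer vector of length
#'   `nchar(t)`).
#' @export
globalAlign <- function(q, t, matrix = blosum62, gapOpen = 11,
                        gapExtend = 1) {
  qs <- as.character(q)
  ts <- as.character(t)
  if (!nzchar(qs) || !nzchar(ts)) stop("sequences must be non-empty")
  checkProtein(qs, "query")
  checkProtein(ts, "target")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qs), Biostrings::AAString(ts),
    substitutionMatrix = matrix, gapOpening = gapOpen,
    gapExtension = gapExtend, type = "global")
  qa <- chars(as.character(Biostrings::alignedPattern(pa)[[1L]]))
  ta <- chars(as.character(Biostrings::alignedSubject(pa)[[1L]]))
  qpos <- cumsum(qa != "-")
  tpos <- cumsum(ta != "-")
  map <- rep(NA_integer_, nchar(ts))
  both <- qa != "-" & ta != "-"
  map[tpos[both]] <- qpos[both]
  st <- alignStats(pa, nchar(qs))
  structure(list(score = Biostrings::score(pa), identity = st$identity,
                 qaln = paste(qa, collapse = ""),
                 taln = paste(ta, collapse = ""), siteMap = map),
            class = "globalAlignment")
}

#' @export
print.alignmentHit <- function(x, ...) {
  cat(sprintf(
    "alignmentHit score=%.1f id=%.1f%% cov=%.1f%% q[%d,%d) t[%d,%d)\n",
    x$score, x$identity, x$coverage, x$qstart, x$qend, x$tstart, x$tend))
  invisible(x)
}
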