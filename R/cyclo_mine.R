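# Cyclotide mining: motif-pattern scanning plus local-alignment homology,
# auto-curation, deduplication and novelty flagging.

#' Bundled cyclotide motif patterns
#'
#' PROSITE-style patterns describing the cyclotide cysteine framework:
#' a generic six-cysteine pattern with family-typical loop-length bounds,
#' a Bracelet-type variant (longer loop 3), a Moebius-type variant
#' (loop 5 constrained to contain Pro), and a relaxed five-cysteine
#' pattern for atypical frameworks that have lost one framework cysteine.
#' These are synthetic stand-ins that encode the framework geometry; users
#' reproducing a database search can substitute the curated family
#' patterns. Note every pattern's maximal span stays within the 40-residue
#' curation window, so a pattern match implies the cysteine-window rule.
#'
#' @return Named character vector of patterns.
#' @export
cyclotidePatterns <- function() {
  c(framework = "C-x(1,6)-C-x(2,8)-C-x(3,9)-C-x(1,3)-C-x(2,8)-C",
    bracelet = "C-x(1,6)-C-x(2,8)-C-x(6,9)-C-x(1,3)-C-x(2,8)-C",
    mobius = "C-x(1,6)-C-x(2,8)-C-x(3,6)-C-x(1,3)-C-x(0,4)-P-x(0,4)-C",
    unusual5 = "C-x(1,6)-C-x(2,8)-C-x(3,11)-C-x(1,8)-C")
}

# auto-curation: >= minCys cysteines within a window of <= windowAa residues
hasCysWindow <- function(s, minCys = 5L, windowAa = 40L) {
  cp <- charPositions(s, "C")
  n <- length(cp)
  if (n < minCys) return(FALSE)
  any(cp[seq_len(n - minCys + 1L) + minCys - 1L] -
        cp[seq_len(n - minCys + 1L)] < windowAa)
}

#' Mine cyclotide-encoding ORFs
#'
#' Candidates are the union of motif-pattern hits ([scanPattern()]) and
#' local-alignment homology hits against reference mature cyclotides
#' (identity and reference coverage thresholds), auto-curated by requiring
#' at least `minCys` cysteines within a `windowAa`-residue window — the
#' reproducible stand-in for manual inspection of hit authenticity.
#'
#' @param orfs `AAStringSet` of candidate ORFs (e.g. from [findOrfsSet()]).
#' @param patterns Character vector of PROSITE-style patterns (or `NULL`).
#' @param refs `AAStringSet` of reference mature cyclotides (or `NULL`).
#' @param minIdentity Minimum percent identity for a homology hit
#'   (default 30).
#' @param minCoverage Minimum percent coverage of the reference
#'   (default 70).
#' @param minCys,windowAa Curation rule parameters (defaults 5 and 40,
#'   tolerant of truncated and unusual frameworks).
#' @return Subset of `orfs` passing mining + curation, with `mcols`
#'   columns `provenance` (`"pattern"`, `"homology"` or
#'   `"pattern+homology"`), `best_ref`, `identity`, `coverage` appended.
#' @export
mineCyclotides <- function(orfs, patterns = cyclotidePatterns(),
                           refs = NULL, minIdentity = 30,
                           minCoverage = 70, minCys = 5L, windowAa = 40L) {
  if ((is.null(patterns) || !length(patterns)) &&
      (is.null(refs) || !length(refs)))
    stop("supply at least one pattern or one reference")
  if (!length(orfs)) return(orfs)
  parsed <- lapply(patterns, parseProsite)
  n <- length(orfs)
  keep <- logical(n)
  provenance <- character(n)
  bestRef <- rep(NA_character_, n)
  bestId <- rep(NA_real_, n)
  bestCov <- rep(NA_real_, n)
  seqsChr <- as.character(orfs)
  for (i in seq_len(n)) {
    s <- seqsChr[[i]]
    # curation is a conjunct of the final rule, so test it first (cheap)
    if (!hasCysWindow(s, minCys, windowAa)) next
    patHit <- length(parsed) > 0L &&
      any(vapply(parsed, function(p) nrow(scanPattern(p, s)) > 0L,
                 logical(1)))
    homHit <- FALSE
    if (!is.null(refs) && length(refs)) {
      for (j in seq_along(refs)) {
        hit <- localAlign(refs[j], s)
        if (hit$identity >= minIdentity && hit$coverage >= minCoverage) {
          homHit <- TRUE
          if (is.na(bestId[i]) || hit$identity > bestId[i]) {
            bestRef[i] <- names(refs)[j]
            bestId[i] <- hit$identity
            bestCov[i] <- hit$coverage
          }
        }
      }
    }
    if (patHit || homHit) {
      keep[i] <- TRUE
      provenance[i] <- paste(
        c(if (patHit) "pattern", if (homHit) "homology"), collapse = "+")
    }
  }
  out <- orfs[keep]
  meta <- S4Vectors::mcols(out)
  meta$provenance <- provenance[keep]
  meta$best_ref <- bestRef[keep]
  meta$identity <- bestId[keep]
  meta$coverage <- bestCov[keep]
  S4Vectors::mcols(out) <- meta
  out
}

#' Deduplicate precursors and mature domains
#'
#' Precursors are unique by full protein string; mature domains by mature
#' sequence. The many-precursors-to-one-domain mapping is preserved
#' (redundant hits encode the same cyclotide with a different signal
#' and/or albumin region). Idempotent.
#'
#' @param precursors `AAStringSet` of candidate precursor proteins.
#' @param domains Optional list of [CyclotideDomain-class] parallel to
#'   `precursors` (`NULL` entries allowed: such candidates are kept in the
#'   precursor set but excluded from domain dedupe, with a warning).
#' @return List with `precursors` (first representative of each unique
#'   protein), `domains` (first representative of each unique mature
#'   sequence), and `mapping` (`data.frame`: `precursor_id`, `domain_id`,
#'   `mature`).
#' @export
dedupe <- function(precursors, domains = NULL) {
  seqs <- as.character(precursors)
  uniqPrec <- precursors[!duplicated(seqs)]
  uniqDom <- list()
  mapping <- NULL
  if (!is.null(domains)) {
    missing <- vapply(domains, is.null, logical(1))
    if (any(missing))
      warning(sum(missing), " candidate(s) lack a parsed mature domain; ",
              "excluded from domain dedupe")
    doms <- domains[!missing]
    if (length(doms)) {
      mats <- vapply(doms, matureSeq, character(1))
      ids <- vapply(doms, function(d) d@id, character(1))
      first <- !duplicated(mats)
      uniqDom <- doms[first]
      domIdOf <- stats::setNames(ids[first], mats[first])
      mapping <- data.frame(precursor_id = ids,
                            domain_id = unname(domIdOf[mats]),
                            mature = mats, row.names = NULL)
    }
  }
  list(precursors = uniqPrec, domains = uniqDom, mapping = mapping)
}

# is 'a' a cyclic rotation of 'b'?
isRotation <- function(a, b) {
  nchar(a) == nchar(b) && grepl(a, paste0(b, b), fixed = TRUE)
}

#' Flag novel mature domains
#'
#' A domain is novel iff its mature sequence matches no reference exactly,
#' nor any cyclic rotation of a reference when both are cyclic (the
#' linear representation of a circular backbone is rotation-ambiguous).
#'
#' @param domains List of [CyclotideDomain-class] objects.
#' @param referenceMature `AAStringSet` of known mature domains; an
#'   optional `cyclic` metadata column marks cyclizable references
#'   (default `TRUE`).
#' @return Named logical vector (`TRUE` = novel).
#' @export
flagNovel <- function(domains, referenceMature) {
  refSeq <- as.character(referenceMature)
  refCyc <- if (!is.null(S4Vectors::mcols(referenceMature)$cyclic))
    S4Vectors::mcols(referenceMature)$cyclic else rep(TRUE, length(refSeq))
  out <- vapply(domains, function(d) {
    m <- matureSeq(d)
    dCyc <- nzchar(d@cyclizationResidue)
    for (j in seq_along(refSeq)) {
      if (m == refSeq[j]) return(FALSE)
      if (dCyc && refCyc[j] && isRotation(m, refSeq[j])) return(FALSE)
    }
    TRUE
  }, logical(1))
  names(out) <- vapply(domains, function(d) d@id, character(1))
  out
}
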