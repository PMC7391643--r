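# Central S4 containers: PrecursorAnnotation, CyclotideDomain, PeakList.
# Coordinate conventions: regions on proteins are 1-based inclusive [start,end];
# nucleotide ORF coordinates (in mcols of findOrfs output) are 0-based
# half-open on the forward strand.

REGION_NAMES <- c("signal", "mature", "linker", "albumin1a", "ctpp")
TOPOLOGIES <- c("mobius", "bracelet", "hybrid", "acyclic", "unusual",
                "unclassified")

#' PrecursorAnnotation: region map of an albumin-1-type cyclotide precursor
#'
#' Records the parsed architecture of a precursor protein: ER signal peptide
#' (ending in the TEA cleavage motif), cyclotide mature domain, linker,
#' albumin-1a chain and C-terminal propeptide, plus completeness flags for
#' truncated (partial) transcripts.
#'
#' @slot id Precursor identifier.
#' @slot regions 5 x 2 integer matrix (rows `signal`, `mature`, `linker`,
#'   `albumin1a`, `ctpp`; columns `start`, `end`), 1-based inclusive on the
#'   protein; `NA` rows mark absent regions.
#' @slot has5p,has3p Logical completeness flags (signal present / albumin-1a
#'   present).
#' @slot cleavageMotif The signal-peptidase motif found (normally `"TEA"`,
#'   `""` when absent).
#' @exportClass PrecursorAnnotation
setClass("PrecursorAnnotation",
  representation(id = "character", regions = "matrix",
                 has5p = "logical", has3p = "logical",
                 cleavageMotif = "character"))

setValidity("PrecursorAnnotation", function(object) {
  r <- object@regions
  if (!identical(rownames(r), REGION_NAMES) || ncol(r) != 2L)
    return("regions must be a 5x2 matrix with the canonical region rows")
  pres <- r[!is.na(r[, 1L]), , drop = FALSE]
  if (nrow(pres)) {
    if (any(pres[, 2L] < pres[, 1L])) return("region end before start")
    if (nrow(pres) > 1L) {
      o <- order(pres[, 1L])
      pres <- pres[o, , drop = FALSE]
      if (any(pres[-1L, 1L] <= pres[-nrow(pres), 2L]))
        return("regions overlap")
      # row order in the canonical matrix must already be genomic order
      if (is.unsorted(match(rownames(pres), REGION_NAMES)))
        return("regions out of architectural order")
    }
  }
  TRUE
})

#' CyclotideDomain: a mature cyclotide with loops and topology
#'
#' The mature six-cysteine domain decomposed into its backbone loops.
#' Loop i (i = 1..5) holds the residues strictly between Cys i and Cys i+1;
#' loop 6 holds the residues after Cys VI up to and including the C-terminal
#' cyclization residue, followed by the residues preceding Cys I (the loop
#' spans the cyclization junction of the circular backbone).
#'
#' @slot id Domain identifier.
#' @slot mature Mature domain sequence (N-terminal flank through the
#'   cyclization residue).
#' @slot cysPositions 1-based cysteine positions within `mature`.
#' @slot loops Character vector of loop sequences (length 6 for the canonical
#'   framework; empty for atypical frameworks).
#' @slot topology One of `mobius`, `bracelet`, `hybrid`, `acyclic`,
#'   `unusual`, `unclassified`.
#' @slot cyclizationResidue `"N"`, `"D"`, or `""` (acyclic).
#' @slot loop1Glu Logical; conserved membrane-binding Glu present in loop 1.
#' @exportClass CyclotideDomain
setClass("CyclotideDomain",
  representation(id = "character", mature = "character",
                 cysPositions = "integer", loops = "character",
                 topology = "character", cyclizationResidue = "character",
                 loop1Glu = "logical"))

setValidity("CyclotideDomain", function(object) {
  if (!object@topology %in% TOPOLOGIES) return("unknown topology label")
  m <- object@mature
  cp <- object@cysPositions
  if (length(cp) && any(chars(m)[cp] != "C"))
    return("cysPositions must point at cysteines")
  if (length(cp) == 6L && length(object@loops) == 6L) {
    # loops interleaved with the cysteines must reconstruct the mature seq
    pre <- substr(m, 1L, cp[1L] - 1L)
    post <- substr(m, cp[6L] + 1L, nchar(m))
    mid <- vapply(1:5, function(i)
      substr(m, cp[i] + 1L, cp[i + 1L] - 1L), character(1))
    rebuilt <- paste0(pre, "C", mid[1L], "C", mid[2L], "C", mid[3L], "C",
                      mid[4L], "C", mid[5L], "C", post)
    if (rebuilt != m) return("cysteine positions inconsistent with mature")
    if (!identical(object@loops[1:5], mid))
      return("loops 1-5 do not match inter-cysteine segments")
    if (object@loops[6L] != paste0(post, pre))
      return("loop 6 must be post-Cys VI tail followed by pre-Cys I flank")
  }
  if (object@topology == "acyclic" && nzchar(object@cyclizationResidue))
    return("acyclic domains have no cyclization residue")
  TRUE
})

#' PeakList: observed MALDI m/z values
#'
#' A sorted list of positive m/z values, interpreted as singly protonated
#' (\[M+H\]+) masses unless `neutral = TRUE`.
#'
#' @slot peaks Numeric vector, sorted ascending, all > 0.
#' @slot label Free-text label (e.g. tissue/fraction).
#' @slot neutral Logical; `TRUE` when the values are neutral masses.
#' @exportClass PeakList
setClass("PeakList",
  representation(peaks = "numeric", label = "character", neutral = "logical"))

setValidity("PeakList", function(object) {
  p <- object@peaks
  if (length(p) && any(!is.finite(p) | p <= 0)) return("peaks must be > 0")
  if (is.unsorted(p)) return("peaks must be sorted ascending")
  TRUE
})

#' Construct a PeakList
#' @param peaks Numeric m/z values (sorted on construction).
#' @param label Optional label.
#' @param neutral Are the values neutral masses rather than \[M+H\]+?
#' @return A [PeakList-class] object.
#' @examples
#' PeakList(c(3110.4, 3072.4))
#' @export
PeakList <- function(peaks = numeric(), label = "", neutral = FALSE) {
  new("PeakList", peaks = sort(as.numeric(peaks)), label = label,
      neutral = neutral)
}

#' @describeIn PeakList-class the m/z values
#' @param x,object A `PeakList`.
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname PeakList-class
#' @export
setMethod("peaks", "PeakList", function(x) x@peaks)

setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList '%s': %d peak(s)%s\n", object@label,
              length(object@peaks),
              if (object@neutral) " [neutral]" else " [M+H]+"))
  if (length(object@peaks))
    cat(" ", paste(head(round(object@peaks, 2), 8L), collapse = ", "),
        if (length(object@peaks) > 8L) "..." else "", "\n")
})

# ---- accessors ----

#' @describeIn CyclotideDomain-class mature domain sequence
#' @param x,object A `CyclotideDomain`.
#' @export
setGeneric("matureSeq", function(x) standardGeneric("matureSeq"))

#' @rdname CyclotideDomain-class
#' @export
setMethod("matureSeq", "CyclotideDomain", function(x) x@mature)

#' @describeIn CyclotideDomain-class the six backbone loops
#' @export
setGeneric("loops", function(x) standardGeneric("loops"))

#' @rdname CyclotideDomain-class
#' @export
setMethod("loops", "CyclotideDomain", function(x) x@loops)

#' @describeIn CyclotideDomain-class topology label
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname CyclotideDomain-class
#' @export
setMethod("topology", "CyclotideDomain", function(x) x@topology)

#' @describeIn CyclotideDomain-class 1-based cysteine positions
#' @export
setGeneric("cysPositions", function(x) standardGeneric("cysPositions"))

#' @rdname CyclotideDomain-class
#' @export
setMethod("cysPositions", "CyclotideDomain", function(x) x@cysPositions)

#' @describeIn CyclotideDomain-class cyclization residue ("N", "D" or "")
#' @export
setGeneric("cyclizationResidue",
           function(x) standardGeneric("cyclizationResidue"))

#' @rdname CyclotideDomain-class
#' @export
setMethod("cyclizationResidue", "CyclotideDomain",
          function(x) x@cyclizationResidue)

setMethod("show", "CyclotideDomain", function(object) {
  cat(sprintf("CyclotideDomain %s [%s] %d Cys\n  %s\n", object@id,
              object@topology, length(object@cysPositions), object@mature))
  if (length(object@loops) == 6L)
    cat("  loops:", paste(sprintf("%d:%s", 1:6, object@loops),
                          collapse = " "), "\n")
})

#' @describeIn PrecursorAnnotation-class region coordinate matrix
#' @param x,object A `PrecursorAnnotation`.
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname PrecursorAnnotation-class
#' @export
setMethod("regions", "PrecursorAnnotation", function(x) x@regions)

#' @describeIn PrecursorAnnotation-class completeness flags, named logical
#' @export
setGeneric("completeness", function(x) standardGeneric("completeness"))

#' @rdname PrecursorAnnotation-class
#' @export
setMethod("completeness", "PrecursorAnnotation",
          function(x) c(has5p = x@has5p, has3p = x@has3p))

setMethod("show", "PrecursorAnnotation", function(object) {
  cat(sprintf("PrecursorAnnotation %s (5':%s 3':%s, motif '%s')\n",
              object@id, object@has5p, object@has3p, object@cleavageMotif))
  r <- object@regions
  for (nm in rownames(r))
    if (!is.na(r[nm, 1L]))
      cat(sprintf("  %-10s %4d-%4d\n", nm, r[nm, 1L], r[nm, 2L]))
})

# internal constructor used by parseArchitecture
newPrecursorAnnotation <- function(id, regions, has5p, has3p, motif) {
  new("PrecursorAnnotation", id = id, regions = regions, has5p = has5p,
      has3p = has3p, cleavageMotif = motif)
}
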