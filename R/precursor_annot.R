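# Albumin-1-type precursor architecture parsing, loop decomposition and
# Moebius/Bracelet/Hybrid topology classification.

#' Bundled linker consensus
#'
#' Ten-residue consensus for the intervening linker between the cyclotide
#' mature domain and the albumin-1a chain. A synthetic stand-in carrying the
#' architectural constraints (length ~10, cysteine-free, free of Asn/Asp so
#' the cyclization-residue window stays unambiguous); editable/replaceable
#' by the user.
#' @return Character scalar.
#' @export
linkerConsensus <- function() "SLVAHLVKAL"

#' Bundled albumin-1a consensus
#'
#' Fifty-residue cysteine-free consensus used to anchor the albumin-1a chain
#' during architecture parsing. Synthetic stand-in; editable.
#' @return Character scalar.
#' @export
alb1aConsensus <- function()
  "ESGFIPEWLRKAAGDVHLMQTYGSLPKEIFDRAGKVQWSTEHLKGMFPRE"

buildMature <- function(pre, l1, l2, l3, l4, l5, l6, cyc = "N") {
  paste0(pre, "C", l1, "C", l2, "C", l3, "C", l4, "C", l5, "C", l6, cyc)
}

#' Labeled topology reference loops
#'
#' Per-family template loops 2 and 3 used by the nearest-reference vote in
#' [classifyTopology()]: Moebius-type sequences carry a short loop 3,
#' Bracelet-type a longer one.
#' @return `data.frame` with columns `label`, `loop2`, `loop3`.
#' @export
topologyReferences <- function() {
  data.frame(
    label = c("mobius", "bracelet"),
    loop2 = c("GETY", "VWIS"),
    loop3 = c("SGKY", "SIFKGL"))
}

#' Reference mature cyclotides
#'
#' A small set of synthetic reference mature domains built from the family
#' templates (one Moebius-like and one Bracelet-like pair), usable as
#' homology queries for mining and as the known-sequence set for novelty
#' flagging. Real surveys would substitute a Cybase export here.
#' @return Named `AAStringSet` with a `label` metadata column.
#' @export
referenceCyclotides <- function() {
  seqs <- c(
    ref_mobius_1 = buildMature("G", "GES", "GETY", "SGKY", "T", "TIPA",
                               "SWSKV"),
    ref_mobius_2 = buildMature("G", "AES", "GETY", "SGKYL", "S", "TLPV",
                               "SWGKL"),
    ref_bracelet_1 = buildMature("G", "AES", "VWIS", "SIFKGL", "T", "TLVA",
                                 "SWGKV"),
    ref_bracelet_2 = buildMature("G", "GES", "VWIS", "SIFKGLAG", "S",
                                 "TVLG", "SWSKL"))
  out <- Biostrings::AAStringSet(seqs)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    label = c("mobius", "mobius", "bracelet", "bracelet"),
    cyclic = TRUE)
  out
}

# maximal groups of cysteine positions with consecutive spacing <= maxGap;
# returns the first group with >= minCys members, or NULL
cysCluster <- function(s, minCys = 5L, maxGap = 12L) {
  cp <- charPositions(s, "C")
  if (!length(cp)) return(NULL)
  grp <- cumsum(c(1L, diff(cp) > maxGap))
  for (g in unique(grp)) {
    mem <- cp[grp == g]
    if (length(mem) >= minCys) return(mem)
  }
  NULL
}

#' Parse albumin-1-type precursor architecture
#'
#' Locates the five architectural regions of a cyclotide precursor:
#' the ER signal peptide is everything up to (and including) the last
#' `TEA` motif preceding the cysteine cluster; the mature domain runs from
#' there to the cyclization residue (first Asn/Asp within `cycWindow`
#' residues after the last framework cysteine); the linker and albumin-1a
#' chain are anchored by local alignment to bundled consensus sequences;
#' the C-terminal propeptide is the remainder. Missing signal or
#' albumin-1a mark the transcript as 5'- or 3'-truncated.
#'
#' @param p Protein sequence (string, `AAString`, or single-record
#'   `AAStringSet`).
#' @param id Identifier (defaults to the record name or `"query"`).
#' @param matureHint Optional `c(start, end)` (1-based inclusive) override
#'   for the mature domain.
#' @param ntermOffset When no TEA motif is found, the mature domain is
#'   taken to start this many residues before Cys I (default 5, covering
#'   atypical N-terminal stretches and non-Gly starts).
#' @param cycWindow Search window (residues after the last framework Cys)
#'   for the Asn/Asp cyclization residue (default 12).
#' @param linkerRef,albRef Consensus anchors, see [linkerConsensus()] and
#'   [alb1aConsensus()].
#' @return A [PrecursorAnnotation-class].
#' @export
parseArchitecture <- function(p, id = NULL, matureHint = NULL,
                              ntermOffset = 5L, cycWindow = 12L,
                              linkerRef = linkerConsensus(),
                              albRef = alb1aConsensus()) {
  s <- if (inherits(p, "AAStringSet")) {
    if (is.null(id)) id <- names(p)[1L]
    as.character(p[[1L]])
  } else as.character(p)
  if (is.null(id)) id <- "query"
  L <- nchar(s)
  cl <- cysCluster(s)
  if (is.null(cl))
    stop("not a cyclotide precursor: no cysteine cluster in '", id, "'")
  firstC <- cl[1L]
  lastC <- cl[length(cl)]
  reg <- matrix(NA_integer_, 5L, 2L,
                dimnames = list(REGION_NAMES, c("start", "end")))
  # --- signal: last TEA motif before the cysteine cluster ---
  motif <- ""
  teaEnd <- NA_integer_
  tea <- gregexpr("TEA", s, fixed = TRUE)[[1L]]
  if (tea[1L] != -1L) {
    ok <- tea[tea + 2L < firstC]
    if (length(ok)) {
      teaEnd <- max(ok) + 2L
      motif <- "TEA"
    }
  }
  has5p <- !is.na(teaEnd)
  if (has5p) reg["signal", ] <- c(1L, teaEnd)
  # --- mature domain ---
  if (!is.null(matureHint)) {
    mStart <- matureHint[1L]
    mEnd <- matureHint[2L]
    cycRes <- substr(s, mEnd, mEnd)
    if (!cycRes %in% c("N", "D")) cycRes <- ""
  } else {
    mStart <- if (has5p) teaEnd + 1L else max(1L, firstC - ntermOffset)
    tailEnd <- min(lastC + cycWindow, L)
    tailSeq <- if (lastC < L) substr(s, lastC + 1L, tailEnd) else ""
    cycPos <- regexpr("[ND]", tailSeq)
    if (cycPos > 0L) {
      mEnd <- lastC + as.integer(cycPos)
      cycRes <- substr(s, mEnd, mEnd)
    } else {
      cycRes <- ""
      # acyclic: anchor the mature end on the linker when findable
      mEnd <- min(lastC + 8L, L)
      if (lastC < L) {
        rest <- substr(s, lastC + 1L, L)
        if (nchar(rest) >= 6L) {
          hit <- localAlign(linkerRef, rest)
          if (hit$identity >= 60 && hit$coverage >= 80 && hit$tstart > 0L)
            mEnd <- lastC + hit$tstart
        }
      }
    }
  }
  reg["mature", ] <- c(mStart, mEnd)
  # --- linker / albumin-1a / CTPP ---
  has3p <- FALSE
  if (mEnd < L) {
    rest <- substr(s, mEnd + 1L, L)
    albFound <- FALSE
    if (nchar(rest) >= 20L) {
      hit <- localAlign(albRef, rest)
      if (hit$identity >= 50 && hit$coverage >= 80) {
        albFound <- TRUE
        albStart <- mEnd + hit$tstart + 1L
        albEnd <- mEnd + hit$tend
        reg["albumin1a", ] <- c(albStart, albEnd)
        if (albStart > mEnd + 1L)
          reg["linker", ] <- c(mEnd + 1L, albStart - 1L)
        if (albEnd < L) reg["ctpp", ] <- c(albEnd + 1L, L)
      }
    }
    if (!albFound && nchar(rest) <= 15L)
      reg["linker", ] <- c(mEnd + 1L, L)
    has3p <- albFound
  }
  newPrecursorAnnotation(id, reg, has5p, has3p, motif)
}

# ungapped per-loop percent identity (left-aligned; denominator = longer)
ungappedIdentity <- function(a, b) {
  la <- nchar(a)
  lb <- nchar(b)
  if (la == 0L && lb == 0L) return(100)
  n <- min(la, lb)
  m <- if (n) sum(chars(substr(a, 1L, n)) == chars(substr(b, 1L, n))) else 0L
  100 * m / max(la, lb)
}

#' Decompose a mature domain into backbone loops
#'
#' @param annotation A [PrecursorAnnotation-class] with a mature region.
#' @param p The precursor protein sequence.
#' @return A [CyclotideDomain-class]. Domains whose cysteine count differs
#'   from six are flagged `unusual` and carry no loop decomposition.
#' @export
extractLoops <- function(annotation, p) {
  s <- if (inherits(p, "AAStringSet")) as.character(p[[1L]])
       else as.character(p)
  r <- regions(annotation)
  if (is.na(r["mature", 1L])) stop("mature region absent")
  mature <- substr(s, r["mature", 1L], r["mature", 2L])
  cp <- charPositions(mature, "C")
  lastRes <- substr(mature, nchar(mature), nchar(mature))
  cycRes <- if (lastRes %in% c("N", "D") &&
                length(cp) && cp[length(cp)] < nchar(mature)) lastRes else ""
  if (length(cp) != 6L) {
    return(new("CyclotideDomain", id = annotation@id, mature = mature,
               cysPositions = cp, loops = character(),
               topology = "unusual",
               cyclizationResidue = if (identical(cycRes, "")) "" else cycRes,
               loop1Glu = NA))
  }
  pre <- substr(mature, 1L, cp[1L] - 1L)
  post <- substr(mature, cp[6L] + 1L, nchar(mature))
  lps <- c(vapply(1:5, function(i)
    substr(mature, cp[i] + 1L, cp[i + 1L] - 1L), character(1)),
    paste0(post, pre))
  topo <- if (cycRes == "") "acyclic" else "unclassified"
  new("CyclotideDomain", id = annotation@id, mature = mature,
      cysPositions = cp, loops = lps, topology = topo,
      cyclizationResidue = cycRes, loop1Glu = grepl("E", lps[1L]))
}

#' Classify cyclotide topology
#'
#' Decision order: `unusual` frameworks are kept; missing cyclization
#' residue means `acyclic`; Pro anywhere in loop 5 (the sequence-level
#' proxy for the cis-Pro bond) means `mobius`; otherwise a
#' nearest-reference vote on ungapped per-loop identity over loops 2 and 3
#' separates `hybrid` (Moebius-like loops without the loop-5 Pro) from
#' `bracelet`, ties falling to `bracelet`. With no references and no Pro
#' the label is `unclassified`.
#'
#' @param d A [CyclotideDomain-class].
#' @param refLoops Labeled reference loops, see [topologyReferences()].
#' @return The domain with its `topology` slot set.
#' @export
classifyTopology <- function(d, refLoops = topologyReferences()) {
  if (d@topology == "unusual") return(d)
  if (d@cyclizationResidue == "") {
    d@topology <- "acyclic"
    return(d)
  }
  if (grepl("P", d@loops[5L], fixed = TRUE)) {
    d@topology <- "mobius"
    return(d)
  }
  if (is.null(refLoops) || !nrow(refLoops)) {
    d@topology <- "unclassified"
    return(d)
  }
  sims <- vapply(seq_len(nrow(refLoops)), function(i) {
    (ungappedIdentity(d@loops[2L], refLoops$loop2[i]) +
       ungappedIdentity(d@loops[3L], refLoops$loop3[i])) / 2
  }, numeric(1))
  best <- max(sims)
  lbls <- refLoops$label[sims == best]
  lbl <- if ("bracelet" %in% lbls) "bracelet" else lbls[1L]
  d@topology <- if (lbl == "mobius") "hybrid" else "bracelet"
  d
}

#' Annotate a precursor end-to-end
#'
#' Convenience wrapper: [parseArchitecture()] then [extractLoops()] then
#' [classifyTopology()].
#'
#' @inheritParams parseArchitecture
#' @param refLoops See [classifyTopology()].
#' @return List with elements `annotation` and `domain`.
#' @export
annotatePrecursor <- function(p, id = NULL, refLoops = topologyReferences(),
                              ...) {
  ann <- parseArchitecture(p, id = id, ...)
  dom <- classifyTopology(extractLoops(ann, p), refLoops)
  list(annotation = ann, domain = dom)
}
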