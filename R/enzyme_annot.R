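# Rule-based annotation of cyclotide-biosynthesis enzymes:
# AEP (ligase vs protease call), PDI, ERO1, cyclophilins.
#
# Reference sequences and site coordinates ship as editable files under
# inst/extdata (synthetic stand-ins carrying the published residue rules);
# site numbering refers to positions in the bundled reference, transferred
# to queries by global alignment.

extdata <- function(f)
  system.file("extdata", f, package = "cyclomine", mustWork = TRUE)

#' Bundled AEP reference with annotated functional sites
#' @return List: `seq` (reference protein string) and `sites`
#'   (`data.frame` with `site`, `pos`): catalytic triad (Asn/His/Cys),
#'   LAD1 positions 1-2 (position 2 = gatekeeper), LAD2 position 1, and
#'   the MLA region boundaries.
#' @export
aepReference <- function() {
  list(seq = as.character(readFasta(extdata("synthetic_aep_ref.fasta"),
                                    "aa")[[1L]]),
       sites = utils::read.delim(extdata("synthetic_aep_sites.tsv")))
}

#' Bundled ERO1 reference with annotated cysteine sites
#' @return List: `seq` and `sites` (`data.frame` with `site`, `role`,
#'   `pos`): outer/inner active-site pairs, regulatory cysteines,
#'   long-range disulfide pair, PDI-interacting pair, one non-catalytic
#'   cysteine.
#' @export
ero1Reference <- function() {
  list(seq = as.character(readFasta(extdata("synthetic_ero1_ref.fasta"),
                                    "aa")[[1L]]),
       sites = utils::read.delim(extdata("synthetic_ero1_sites.tsv")))
}

#' Bundled thioredoxin-fold consensus (CGHC active site)
#' @return Character scalar (100 aa).
#' @export
trxConsensus <- function()
  as.character(readFasta(extdata("synthetic_trx_consensus.fasta"),
                         "aa")[[1L]])

#' Bundled cyclophilin-like-domain reference
#' @return Character scalar (90 aa).
#' @export
cldReference <- function()
  as.character(readFasta(extdata("synthetic_cld_ref.fasta"), "aa")[[1L]])

siteLetter <- function(q, map, pos) {
  qp <- map[pos]
  if (is.na(qp)) NA_character_ else substr(q, qp, qp)
}

#' Annotate an asparaginyl endopeptidase (ligase vs protease call)
#'
#' Transfers the reference's functional sites to the query by global
#' alignment, then applies the residue rules: ligase-like requires a
#' complete Asn-His-Cys catalytic triad, a bulky aromatic (F/Y/W) at LAD1
#' position 1, V/I/C/A (not Gly) at LAD1 position 2 (the gatekeeper), and
#' Gly/Ala at LAD2 position 1; a Gly or Ser gatekeeper marks a
#' protease-like AEP; anything else (or an incomplete triad) is ambiguous.
#' The MLA segment length is reported as informational only.
#'
#' @param q Query protein (string or `AAString`/`AAStringSet` element).
#' @param ref Reference list as returned by [aepReference()].
#' @return List of class `"aepAnnotation"`: `triad` (letters + positions +
#'   `complete` flag), `gk`, `lad1`, `lad2`, `mlaLength`, `call`.
#' @export
annotateAep <- function(q, ref = aepReference()) {
  qs <- if (inherits(q, "AAStringSet")) as.character(q[[1L]])
        else as.character(q)
  ga <- globalAlign(qs, ref$seq)
  map <- ga$siteMap
  sp <- stats::setNames(ref$sites$pos, ref$sites$site)
  lt <- function(site) siteLetter(qs, map, sp[[site]])
  triad <- c(asn = lt("triad_asn"), his = lt("triad_his"),
             cys = lt("triad_cys"))
  triadComplete <- !anyNA(triad) &&
    all(triad == c(asn = "N", his = "H", cys = "C"))
  gk <- lt("gk")
  lad1 <- c(lt("lad1_1"), lt("lad1_2"))
  lad2 <- lt("lad2_1")
  mlaLength <- {
    a <- map[sp[["mla_start"]]]
    b <- map[sp[["mla_end"]]]
    if (is.na(a) || is.na(b)) NA_integer_ else b - a + 1L
  }
  call <- if (!triadComplete) "ambiguous"
    else if (!anyNA(lad1) && lad1[1L] %in% c("F", "Y", "W") &&
             lad1[2L] %in% c("V", "I", "C", "A") &&
             !is.na(lad2) && lad2 %in% c("G", "A")) "ligase_like"
    else if (!is.na(gk) && gk %in% c("G", "S")) "protease_like"
    else "ambiguous"
  structure(list(triad = triad, triadComplete = triadComplete, gk = gk,
                 lad1 = lad1, lad2 = lad2, mlaLength = mlaLength,
                 call = call),
            class = "aepAnnotation")
}

#' @export
print.aepAnnotation <- function(x, ...) {
  cat(sprintf("AEP annotation: %s (triad %s, GK=%s, LAD1=%s%s, LAD2=%s)\n",
              x$call, if (x$triadComplete) "complete" else "incomplete",
              x$gk, x$lad1[1L], x$lad1[2L], x$lad2))
  invisible(x)
}

#' Annotate a protein disulfide isomerase
#'
#' Detects thioredoxin-fold segments by iterated local alignment to a
#' bundled fold consensus (each accepted hit is masked and the scan
#' repeated), labels each segment catalytic (`a`-type, contains a CXXC
#' tetrapeptide) or non-catalytic (`b`-type), builds the domain
#' arrangement string (e.g. `"a-b-b'-a'"`), and tests the C-terminal
#' tetrapeptide against the ER-retention consensus `[KHN][DE]EL`;
#' non-canonical tails (e.g. `KDQI`) are reported verbatim.
#'
#' @param q Query protein.
#' @param consensus Thioredoxin-fold consensus (see [trxConsensus()]).
#' @param minIdentity Minimum percent identity for a fold hit (default 30).
#' @param minCoverage Minimum consensus coverage (default 60).
#' @return List of class `"pdiAnnotation"`: `activeSites` (`data.frame`
#'   `pos`, `motif`), `segments` (`data.frame` `start`, `end`, `type`),
#'   `arrangement`, `erTetrapeptide`, `canonicalEr`.
#' @export
annotatePdi <- function(q, consensus = trxConsensus(), minIdentity = 30,
                        minCoverage = 60) {
  qs <- if (inherits(q, "AAStringSet")) as.character(q[[1L]])
        else as.character(q)
  masked <- qs
  segs <- list()
  for (iter in 1:8) {
    hit <- localAlign(consensus, masked)
    if (hit$score <= 0 || hit$identity < minIdentity ||
        hit$coverage < minCoverage) break
    segs[[length(segs) + 1L]] <- c(start = hit$tstart + 1L, end = hit$tend)
    substr(masked, hit$tstart + 1L, hit$tend) <-
      strrep("X", hit$tend - hit$tstart)
  }
  segments <- if (length(segs)) {
    df <- as.data.frame(do.call(rbind, segs))
    df <- df[order(df$start), , drop = FALSE]
    df$type <- vapply(seq_len(nrow(df)), function(i)
      if (nrow(scanPattern("C-x(2)-C",
                           substr(qs, df$start[i], df$end[i]))) > 0L)
        "a" else "b", character(1))
    df
  } else data.frame(start = integer(), end = integer(),
                    type = character())
  # arrangement: successive a/b types primed in N->C order
  arrangement <- if (nrow(segments)) {
    cnt <- c(a = 0L, b = 0L)
    paste(vapply(segments$type, function(tp) {
      lab <- paste0(tp, strrep("'", cnt[[tp]]))
      cnt[[tp]] <<- cnt[[tp]] + 1L
      lab
    }, character(1)), collapse = "-")
  } else ""
  activeSites <- do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
    if (segments$type[i] != "a") return(NULL)
    m <- scanPattern("C-x(2)-C", substr(qs, segments$start[i],
                                        segments$end[i]))
    data.frame(pos = segments$start[i] + m[, "start"],
               motif = substring(qs, segments$start[i] + m[, "start"],
                                 segments$start[i] + m[, "end"] - 1L))
  }))
  if (is.null(activeSites))
    activeSites <- data.frame(pos = integer(), motif = character())
  tail4 <- if (nchar(qs) >= 4L) substr(qs, nchar(qs) - 3L, nchar(qs)) else qs
  structure(list(activeSites = activeSites, segments = segments,
                 arrangement = arrangement, erTetrapeptide = tail4,
                 canonicalEr = grepl("^[KHN][DE]EL$", tail4)),
            class = "pdiAnnotation")
}

#' @export
print.pdiAnnotation <- function(x, ...) {
  cat(sprintf("PDI annotation: arrangement %s, %d CXXC site(s), C-term %s%s\n",
              if (nzchar(x$arrangement)) x$arrangement else "(none)",
              nrow(x$activeSites), x$erTetrapeptide,
              if (x$canonicalEr) " [canonical ER retention]"
              else " [non-canonical]"))
  invisible(x)
}

#' Annotate an ER oxidoreductin-1 candidate
#'
#' Maps each annotated reference cysteine (outer/inner active sites,
#' regulatory set, long-range pair, PDI-interacting pair, non-catalytic)
#' to the query through a global-alignment site map and reports its
#' status: conserved cysteine, substituted (with the substituting
#' residue), or absent (unalignable).
#'
#' @param q Query protein.
#' @param ref Reference list as returned by [ero1Reference()].
#' @return `data.frame` of class `"ero1Annotation"` with columns `site`,
#'   `role`, `refPos`, `qPos`, `residue`, `status`.
#' @export
annotateEro1 <- function(q, ref = ero1Reference()) {
  qs <- if (inherits(q, "AAStringSet")) as.character(q[[1L]])
        else as.character(q)
  ga <- globalAlign(qs, ref$seq)
  map <- ga$siteMap
  qPos <- map[ref$sites$pos]
  residue <- vapply(qPos, function(p)
    if (is.na(p)) NA_character_ else substr(qs, p, p), character(1))
  status <- ifelse(is.na(qPos), "absent",
                   ifelse(residue == "C", "conserved", "substituted"))
  out <- data.frame(site = ref$sites$site, role = ref$sites$role,
                    refPos = ref$sites$pos, qPos = qPos,
                    residue = residue, status = status)
  class(out) <- c("ero1Annotation", class(out))
  out
}

#' Annotate a cyclophilin / PPIase candidate
#'
#' Locates the cyclophilin-like domain (CLD) by local alignment to a
#' reference CLD; a query is called multi-domain when at least
#' `minFlank` residues flank the CLD on either side and an auxiliary
#' motif (default a zinc-finger-like pattern) matches that flank,
#' otherwise flanks are reported unannotated.
#'
#' @param q Query protein.
#' @param cldRef Reference CLD (see [cldReference()]).
#' @param auxPattern PROSITE-style auxiliary-domain pattern.
#' @param minIdentity,minCoverage CLD acceptance thresholds
#'   (defaults 30 / 70, coverage of the reference).
#' @param minFlank Minimum flank length to consider (default 20 aa).
#' @return List of class `"cypAnnotation"`: `cldFound`, `cldStart`,
#'   `cldEnd` (1-based, query), `multiDomain`, `auxFlank`
#'   (`"N"`, `"C"` or `NA`).
#' @export
annotateCyp <- function(q, cldRef = cldReference(),
                        auxPattern = "C-x(2)-C-x(4)-H-x(4)-C",
                        minIdentity = 30, minCoverage = 70,
                        minFlank = 20L) {
  qs <- if (inherits(q, "AAStringSet")) as.character(q[[1L]])
        else as.character(q)
  hit <- localAlign(cldRef, qs)
  if (hit$score <= 0 || hit$identity < minIdentity ||
      hit$coverage < minCoverage)
    return(structure(list(cldFound = FALSE, cldStart = NA_integer_,
                          cldEnd = NA_integer_, multiDomain = FALSE,
                          auxFlank = NA_character_),
                     class = "cypAnnotation"))
  cldStart <- hit$tstart + 1L
  cldEnd <- hit$tend
  multi <- FALSE
  auxFlank <- NA_character_
  flanks <- c(N = substr(qs, 1L, cldStart - 1L),
              C = substr(qs, cldEnd + 1L, nchar(qs)))
  for (side in names(flanks)) {
    fl <- flanks[[side]]
    if (nchar(fl) >= minFlank && nrow(scanPattern(auxPattern, fl)) > 0L) {
      multi <- TRUE
      auxFlank <- side
      break
    }
  }
  structure(list(cldFound = TRUE, cldStart = cldStart, cldEnd = cldEnd,
                 multiDomain = multi, auxFlank = auxFlank),
            class = "cypAnnotation")
}
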