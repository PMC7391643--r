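# Peptide mass engine: monoisotopic/average masses for linear or
# head-to-tail cyclic, reduced or disulfide-oxidized peptides, and
# matching of predicted [M+H]+ values to MALDI peak lists.

MONO_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

AVG_RESIDUE <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

MASS_WATER_MONO <- 18.010565
MASS_WATER_AVG <- 18.01528
MASS_H <- 1.0078250319
MASS_PROTON <- 1.00728

#' Peptide mass
#'
#' Mass of a peptide: sum of residue masses plus one water for a linear
#' chain; head-to-tail cyclization removes the water; each disulfide bond
#' removes two hydrogens.
#'
#' @param seq Peptide sequence over the 20 standard residues.
#' @param cyclic Head-to-tail cyclic backbone?
#' @param nDisulfides Number of disulfide bonds (<= floor(#Cys / 2)).
#' @param kind `"monoisotopic"` or `"average"`.
#' @return Mass in Da.
#' @examples
#' peptideMass("G")                                   # 75.03203
#' peptideMass("GLPVCGETCVGGTCNTPGCTCSWPVCTRN",
#'             cyclic = TRUE, nDisulfides = 3)
#' @export
peptideMass <- function(seq, cyclic = FALSE, nDisulfides = 0L,
                        kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  s <- as.character(seq)
  checkProtein(s, "peptide", allowX = FALSE)
  v <- chars(s)
  nCys <- sum(v == "C")
  if (nDisulfides > nCys %/% 2L)
    stop("nDisulfides exceeds floor(#Cys / 2)")
  tab <- if (kind == "monoisotopic") MONO_RESIDUE else AVG_RESIDUE
  water <- if (kind == "monoisotopic") MASS_WATER_MONO else MASS_WATER_AVG
  sum(tab[v]) + (!cyclic) * water - 2 * MASS_H * nDisulfides
}

#' Singly protonated mass \[M+H\]+
#'
#' @param neutral Neutral mass (Da).
#' @param convention `"proton"` adds the proton mass 1.00728; `"unit"` adds
#'   1.0, the convention used when spectra report "M + H" as m/z + 1.
#' @return \[M+H\]+ in Da.
#' @examples
#' computeMh(3071.4, "unit")    # 3072.4
#' @export
computeMh <- function(neutral, convention = c("proton", "unit")) {
  convention <- match.arg(convention)
  neutral + if (convention == "proton") MASS_PROTON else 1.0
}

#' Mass records for a set of peptides
#'
#' @param ids Peptide identifiers.
#' @param seqs Peptide sequences.
#' @param cyclic Logical (recycled): head-to-tail cyclic backbone.
#' @param nDisulfides Integer (recycled): disulfide bonds.
#' @param convention \[M+H\]+ convention, see [computeMh()].
#' @return `data.frame` with columns `id`, `seq`, `cyclic`, `n_disulfides`,
#'   `monoisotopic`, `average`, `mh`.
#' @export
massRecords <- function(ids, seqs, cyclic = FALSE, nDisulfides = 0L,
                        convention = c("proton", "unit")) {
  convention <- match.arg(convention)
  n <- length(seqs)
  cyclic <- rep_len(cyclic, n)
  nDisulfides <- rep_len(as.integer(nDisulfides), n)
  mono <- mapply(peptideMass, seqs, cyclic, nDisulfides,
                 MoreArgs = list(kind = "monoisotopic"))
  avg <- mapply(peptideMass, seqs, cyclic, nDisulfides,
                MoreArgs = list(kind = "average"))
  data.frame(id = ids, seq = as.character(seqs), cyclic = cyclic,
             n_disulfides = nDisulfides, monoisotopic = mono, average = avg,
             mh = computeMh(mono, convention), row.names = NULL)
}

#' Mass records for cyclotide domains
#'
#' Mature cyclotides are matched in their in-planta form: fully oxidized
#' (all cysteines paired) and backbone-cyclized when a cyclization residue
#' is present; acyclic domains are matched as linear oxidized peptides.
#'
#' @param domains List of [CyclotideDomain-class] objects.
#' @inheritParams massRecords
#' @return See [massRecords()].
#' @export
domainMassRecords <- function(domains, convention = c("proton", "unit")) {
  convention <- match.arg(convention)
  ids <- vapply(domains, function(d) d@id, character(1))
  seqs <- vapply(domains, matureSeq, character(1))
  cyc <- vapply(domains, function(d) nzchar(d@cyclizationResidue), logical(1))
  nss <- vapply(domains, function(d) length(d@cysPositions) %/% 2L,
                integer(1))
  massRecords(ids, seqs, cyclic = cyc, nDisulfides = nss,
              convention = convention)
}

#' Match predicted masses to observed peaks
#'
#' Reports every (peak, record) pair whose difference is within the
#' tolerance. The match set is monotone non-decreasing in `tol`.
#'
#' @param records [massRecords()] data frame (column `mh` is compared, or
#'   `monoisotopic` when the peak list is flagged neutral).
#' @param peakList A [PeakList-class] (or numeric vector of \[M+H\]+ m/z).
#' @param tol Tolerance in Da (> 0), or in ppm when `ppm = TRUE`.
#' @param ppm Interpret `tol` as parts-per-million of the observed peak.
#' @return `data.frame` with columns `peak`, `id`, `predicted`, `delta`
#'   (observed - predicted) and `tol`, sorted by peak then `|delta|`.
#' @export
matchPeaks <- function(records, peakList, tol = 0.5, ppm = FALSE) {
  if (tol <= 0) stop("'tol' must be > 0")
  neutral <- FALSE
  pk <- if (inherits(peakList, "PeakList")) {
    neutral <- peakList@neutral
    peaks(peakList)
  } else sort(as.numeric(peakList))
  pred <- if (neutral) records$monoisotopic else records$mh
  out <- list()
  for (p in pk) {
    lim <- if (ppm) p * tol * 1e-6 else tol
    d <- p - pred
    hit <- which(abs(d) <= lim)
    if (length(hit)) {
      hit <- hit[order(abs(d[hit]))]
      out[[length(out) + 1L]] <- data.frame(
        peak = p, id = records$id[hit], predicted = pred[hit],
        delta = d[hit], tol = lim)
    }
  }
  if (!length(out))
    return(data.frame(peak = numeric(), id = character(),
                      predicted = numeric(), delta = numeric(),
                      tol = numeric()))
  do.call(rbind, out)
}
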