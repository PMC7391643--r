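# End-to-end workflow: simulate (or load) transcripts -> six-frame ORFs ->
# mine -> parse architecture / classify topology -> dedupe -> novelty ->
# mass-match, with a summary table.

#' Run the cyclotide discovery pipeline on synthetic or supplied data
#'
#' Chains the package's stages: transcript generation (when `cfg` is a
#' [simConfig()]) or user transcripts, six-frame ORF extraction (open
#' stop-to-stop segments, minimum 50 aa), motif + homology mining with
#' cysteine-window curation, precursor architecture parsing, loop
#' decomposition and topology classification, deduplication, novelty
#' flagging against the reference set, and mass matching of a MALDI peak
#' list (synthetic when simulating).
#'
#' @param cfg A [simConfig()] (synthetic run), or a list with elements
#'   `transcripts` (named `DNAStringSet`) and optionally `peakList`.
#' @param refs Reference mature cyclotides for homology mining and
#'   novelty flagging (default [referenceCyclotides()]).
#' @param patterns Motif patterns for mining (default
#'   [cyclotidePatterns()]).
#' @param tol Mass-match tolerance in Da.
#' @param minAa Minimum ORF length (default 50).
#' @param outDir Optional directory: writes `summary.tsv`,
#'   `candidates.fasta`, `domains.tsv`, `matches.tsv` and a parameter log.
#' @return List: `orfs`, `candidates`, `annotations`, `domains` (unique),
#'   `mapping`, `novel`, `massRecords`, `matches`, `summary` (one-row
#'   `data.frame` of counts and the topology tally), and — for synthetic
#'   runs — `truth` and `evaluation` (`decoyFalsePositives`,
#'   `topologyAccuracy`, `precursorsRecovered`).
#' @export
runPipeline <- function(cfg, refs = referenceCyclotides(),
                        patterns = cyclotidePatterns(), tol = 0.5,
                        minAa = 50L, outDir = NULL) {
  synthetic <- inherits(cfg, "simConfig")
  if (synthetic) {
    gen <- generatePrecursorSet(cfg)
    transcripts <- gen$transcripts
    truth <- gen$truth
  } else {
    transcripts <- cfg$transcripts
    truth <- NULL
  }
  orfs <- findOrfsSet(transcripts, minAa = minAa)
  open <- orfs[S4Vectors::mcols(orfs)$variant == "open"]
  cands <- mineCyclotides(open, patterns = patterns, refs = refs)
  anns <- vector("list", length(cands))
  doms <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    res <- tryCatch(
      annotatePrecursor(as.character(cands[[i]]), id = names(cands)[i]),
      error = function(e) NULL)
    if (!is.null(res)) {
      anns[[i]] <- res$annotation
      doms[[i]] <- res$domain
    }
  }
  dd <- dedupe(cands, doms)
  novel <- if (length(dd$domains)) flagNovel(dd$domains, refs)
           else logical()
  recs <- if (length(dd$domains)) domainMassRecords(dd$domains)
          else NULL
  peakList <- if (synthetic) generatePeakList(dd$domains, cfg)$peakList
              else cfg$peakList
  matches <- if (!is.null(recs) && !is.null(peakList) &&
                 length(peaks(peakList)))
    matchPeaks(recs, peakList, tol = tol)
  else data.frame()
  topoTally <- table(factor(
    vapply(dd$domains, topology, character(1)), levels = TOPOLOGIES))
  summary <- data.frame(
    n_transcripts = length(transcripts), n_orfs = length(open),
    n_candidates = length(cands),
    n_precursors = length(dd$precursors),
    n_unique_domains = length(dd$domains),
    n_novel = sum(novel), as.list(topoTally),
    n_peaks = if (is.null(peakList)) 0L else length(peaks(peakList)),
    n_peak_matches = if (nrow(matches))
      length(unique(matches$peak)) else 0L)
  out <- list(orfs = orfs, candidates = cands, annotations = anns,
              domains = dd$domains, mapping = dd$mapping, novel = novel,
              massRecords = recs, matches = matches, summary = summary)
  if (synthetic) {
    src <- S4Vectors::mcols(cands)$source_id
    isDecoy <- truth$is_decoy[match(src, truth$id)]
    predTopo <- vapply(doms, function(d)
      if (is.null(d)) NA_character_ else topology(d), character(1))
    trueTopo <- truth$topology[match(src, truth$id)]
    cycTrue <- which(!truth$is_decoy)
    out$truth <- truth
    out$evaluation <- list(
      decoyFalsePositives = sum(isDecoy, na.rm = TRUE),
      precursorsRecovered = length(intersect(src, truth$id[cycTrue])),
      topologyAccuracy = if (any(!isDecoy))
        mean(predTopo[!isDecoy] == trueTopo[!isDecoy], na.rm = TRUE)
      else NA_real_)
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(summary, file.path(outDir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeFasta(cands, file.path(outDir, "candidates.fasta"))
    if (length(dd$domains)) {
      domTab <- data.frame(
        id = vapply(dd$domains, function(d) d@id, character(1)),
        mature = vapply(dd$domains, matureSeq, character(1)),
        topology = vapply(dd$domains, topology, character(1)),
        cyclization = vapply(dd$domains, cyclizationResidue, character(1)),
        novel = novel)
      utils::write.table(domTab, file.path(outDir, "domains.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (nrow(matches))
      utils::write.table(matches, file.path(outDir, "matches.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    params <- if (synthetic) unlist(cfg[c("nCyclotide", "nDecoy",
                                          "truncationProb", "seed")])
              else c(n_transcripts = length(transcripts))
    writeLines(c(sprintf("tol\t%s", tol), sprintf("minAa\t%s", minAa),
                 paste(names(params), params, sep = "\t")),
               file.path(outDir, "parameters.log"))
  }
  out
}
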