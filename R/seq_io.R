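# FASTA / peak-list / TPM-table I/O and six-frame ORF extraction.

# standard codon table 1; any codon containing N (or other ambiguity) -> X
CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  # third base varies fastest, first slowest (standard table layout)
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), 4L),
                   rep(bases, 16L))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "", fixed = TRUE)[[1L]]
  stats::setNames(aa, codons)
})

translateCodons <- function(codons) {
  aa <- CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# translate a nucleotide string (length divisible by 3)
translateNt <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("length not divisible by 3")
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  translateCodons(codons)
}

revComp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Read a FASTA file
#'
#' Reads nucleotide or amino-acid FASTA into a `DNAStringSet` /
#' `AAStringSet`. Sequences are uppercased, a trailing `*` (stop) is stripped
#' from protein records, duplicate ids are an error, and the alphabet is
#' validated (`A/C/G/T/N` for `nt`, the 20 residues plus `X` for `aa`).
#'
#' @param path Path to the FASTA file.
#' @param alphabet `"nt"` or `"aa"`.
#' @return A `DNAStringSet` or `AAStringSet`, in file order.
#' @export
readFasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(if (alphabet == "nt") Biostrings::DNAStringSet()
           else Biostrings::AAStringSet())
  }
  hdr <- startsWith(lines, ">")
  if (!hdr[1L])
    stop("malformed FASTA: line 1 does not start with '>'")
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  if (any(!nzchar(ids))) {
    bad <- which(hdr)[!nzchar(ids)][1L]
    stop("malformed FASTA header at line ", bad)
  }
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  out <- character(length(ids))
  names(out) <- ids
  out[as.integer(names(seqs))] <- toupper(seqs)
  if (alphabet == "aa") out <- sub("\\*$", "", out)
  ok <- if (alphabet == "nt") NT5 else AA21
  for (i in seq_along(out)) {
    bad <- setdiff(unique(chars(out[i])), ok)
    if (length(bad))
      stop(sprintf("illegal %s character(s) %s in record '%s'", alphabet,
                   paste(bad, collapse = ","), ids[i]))
  }
  if (alphabet == "nt") Biostrings::DNAStringSet(out)
  else Biostrings::AAStringSet(out)
}

#' Write sequences to FASTA
#'
#' @param records Named character vector or `XStringSet`.
#' @param path Output path.
#' @param width Line width for wrapped sequence lines (>= 1).
#' @return `path`, invisibly. Round-trips with [readFasta()].
#' @export
writeFasta <- function(records, path, width = 60L) {
  if (width < 1L) stop("'width' must be >= 1")
  ids <- names(records)
  seqs <- as.character(records)
  if (is.null(ids) && length(seqs)) stop("records must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    n <- nchar(s)
    if (n)
      writeLines(substring(s, seq(1L, n, width),
                           pmin(seq(width, n + width - 1L, width), n)), con)
  }
  invisible(path)
}

#' Find open reading frames in all six frames
#'
#' Enumerates maximal stop-to-stop segments in every reading frame of a
#' transcript and reports, for each segment of at least `minAa` residues,
#' an `"open"` variant (the full segment, matching long-ORF extraction from
#' assemblies whose transcripts may lack 5' ends) and, when the segment
#' contains a Met, an `"atg"` variant starting at the first Met (reported
#' when it also reaches `minAa` and differs from the open variant).
#' Codons containing `N` translate to `X`.
#'
#' @param transcript A single-element named `DNAStringSet`, or a nucleotide
#'   string (then `id` must be given).
#' @param minAa Minimum ORF length in amino acids (default 50).
#' @param id Transcript id when `transcript` is a bare string.
#' @return An `AAStringSet` with `mcols` columns `source_id`, `frame`
#'   (+1..+3/-1..-3), `start`, `end` (0-based half-open forward-strand
#'   nucleotide coordinates of the ORF, stop codon excluded; for negative
#'   frames, the coordinates of the reverse-complement ORF on the forward
#'   strand) and `variant` (`"open"` or `"atg"`).
#' @export
findOrfs <- function(transcript, minAa = 50L, id = NULL) {
  if (inherits(transcript, "DNAStringSet")) {
    stopifnot(length(transcript) == 1L)
    id <- names(transcript)
    nt <- as.character(transcript[[1L]])
  } else {
    nt <- toupper(as.character(transcript))
    if (is.null(id)) stop("'id' required for a bare sequence")
  }
  if (minAa < 1L) stop("'minAa' must be >= 1")
  L <- nchar(nt)
  res <- list()
  strands <- list(`+` = nt, `-` = if (L) revComp(nt) else nt)
  for (strand in names(strands)) {
    s <- strands[[strand]]
    for (off in 0:2) {
      nCod <- (L - off) %/% 3L
      if (nCod < minAa) next
      sub <- substr(s, off + 1L, off + 3L * nCod)
      aa <- translateNt(sub)
      # maximal stop-free segments with their codon offsets
      m <- gregexpr("[^*]+", aa)[[1L]]
      if (m[1L] == -1L) next
      for (k in seq_along(m)) {
        segStart <- m[k] - 1L                      # 0-based codon index
        segLen <- attr(m, "match.length")[k]
        seg <- substr(aa, m[k], m[k] + segLen - 1L)
        starts <- c(open = 0L)
        mpos <- regexpr("M", seg, fixed = TRUE)
        if (mpos > 0L && mpos > 1L) starts <- c(starts, atg = mpos - 1L)
        for (variant in names(starts)) {
          d <- starts[[variant]]
          pep <- substr(seg, d + 1L, segLen)
          if (nchar(pep) < minAa) next
          c0 <- off + 3L * (segStart + d)          # 0-based nt, this strand
          c1 <- off + 3L * (segStart + segLen)
          if (strand == "+") { fs <- c0; fe <- c1 }
          else { fs <- L - c1; fe <- L - c0 }
          frame <- if (strand == "+") off + 1L else -(off + 1L)
          res[[length(res) + 1L]] <- list(
            seq = pep, frame = frame, start = fs, end = fe,
            variant = variant)
        }
      }
    }
  }
  if (!length(res)) {
    out <- Biostrings::AAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      source_id = character(), frame = integer(), start = integer(),
      end = integer(), variant = character())
    return(out)
  }
  seqs <- vapply(res, `[[`, character(1), "seq")
  meta <- S4Vectors::DataFrame(
    source_id = rep(id, length(res)),
    frame = vapply(res, `[[`, integer(1), "frame"),
    start = vapply(res, `[[`, numeric(1), "start"),
    end = vapply(res, `[[`, numeric(1), "end"),
    variant = vapply(res, `[[`, character(1), "variant"))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- sprintf("%s|f%+d|%d-%d|%s", id, meta$frame, meta$start,
                        meta$end, meta$variant)
  S4Vectors::mcols(out) <- meta
  out
}

#' Find ORFs across a set of transcripts
#'
#' @param transcripts A named `DNAStringSet`.
#' @inheritParams findOrfs
#' @return Concatenated [findOrfs()] output for all transcripts.
#' @export
findOrfsSet <- function(transcripts, minAa = 50L) {
  outs <- lapply(seq_along(transcripts), function(i)
    findOrfs(transcripts[i], minAa = minAa))
  seqs <- do.call(c, lapply(outs, as.character))
  out <- Biostrings::AAStringSet(seqs)
  S4Vectors::mcols(out) <- do.call(rbind, lapply(outs, S4Vectors::mcols))
  out
}

#' Read a MALDI peak list
#'
#' One m/z value per line (an optional second, tab-separated intensity
#' column is ignored). Values are sorted ascending.
#'
#' @param path Path to the TSV file.
#' @param label Label for the list (defaults to the file name).
#' @param neutral Are values neutral masses rather than \[M+H\]+?
#' @return A [PeakList-class].
#' @export
readPeakList <- function(path, label = basename(path), neutral = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vals <- vapply(strsplit(lines, "[\t,]"), `[`, character(1), 1L)
  mz <- suppressWarnings(as.numeric(vals))
  if (anyNA(mz))
    stop("non-numeric m/z at line ", which(is.na(mz))[1L])
  if (any(mz <= 0)) stop("m/z values must be positive")
  PeakList(mz, label = label, neutral = neutral)
}

#' Read a TPM expression table
#'
#' Tab-separated, header row of sample/tissue ids, first column gene ids.
#' Validates rectangularity, uniqueness of ids and non-negativity.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (genes x samples).
#' @export
readExpression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, row.names = NULL)
  if (ncol(df) < 2L) stop("expression table needs gene ids plus >= 1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate gene id(s)")
  if (anyDuplicated(colnames(df)[-1L])) stop("duplicate sample id(s)")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2L,
                                              as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric TPM at row %s, column %s",
                 ids[bad[1L, 1L]], colnames(df)[-1L][bad[1L, 2L]]))
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("missing TPM at row %s, column %s",
                 ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)
    stop(sprintf("negative TPM at row %s, column %s",
                 ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  rownames(m) <- ids
  m
}

#' Write a TPM expression table
#' @param m Numeric matrix (genes x samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
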