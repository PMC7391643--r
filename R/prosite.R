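# PROSITE-style pattern parsing and scanning.
#
# Supported syntax: elements separated by '-'; each element is a residue
# letter, 'x' (any), a class '[ACD]' or negated class '{ACD}', optionally
# followed by a repeat '(n)' or '(n,m)'; '<' anchors the pattern to the
# N terminus and '>' to the C terminus.

#' Parse a PROSITE-style pattern
#'
#' @param pattern Pattern string, e.g. `"C-x(3)-C"` or `"<M-x(2,5)-[ED]>"`.
#' @return An object of class `"prositePattern"`: a list of elements, each
#'   with an allowed-residue set and a repeat range, plus anchor flags.
#' @export
parseProsite <- function(pattern) {
  p <- gsub("\\.$", "", trimws(pattern))
  anchorN <- startsWith(p, "<")
  if (anchorN) p <- substr(p, 2L, nchar(p))
  anchorC <- endsWith(p, ">")
  if (anchorC) p <- substr(p, 1L, nchar(p) - 1L)
  if (!nzchar(p)) stop("empty pattern")
  toks <- strsplit(p, "-", fixed = TRUE)[[1L]]
  if (any(!nzchar(toks)))
    stop("syntax error in pattern '", pattern, "': empty element at position ",
         which(!nzchar(toks))[1L])
  elements <- lapply(seq_along(toks), function(i) {
    tok <- toks[i]
    m <- regmatches(tok, regexec(
      "^(x|[A-WYZ]|\\[[A-Z]+\\]|\\{[A-Z]+\\})(\\((\\d+)(,(\\d+))?\\))?$",
      tok))[[1L]]
    if (!length(m))
      stop("syntax error in pattern '", pattern, "' at element ", i,
           " ('", tok, "')")
    base <- m[2L]
    lo <- if (nzchar(m[4L])) as.integer(m[4L]) else 1L
    hi <- if (nzchar(m[6L])) as.integer(m[6L]) else lo
    if (hi < lo) stop("repeat range reversed at element ", i)
    allowed <- if (base == "x") AA21
      else if (startsWith(base, "[")) chars(gsub("[][]", "", base))
      else if (startsWith(base, "{"))
        setdiff(AA20, chars(gsub("[{}]", "", base)))
      else base
    list(allowed = allowed, lo = lo, hi = hi)
  })
  structure(list(elements = elements, anchorN = anchorN, anchorC = anchorC,
                 pattern = pattern), class = "prositePattern")
}

# greedy depth-first match of elements k.. starting at 0-based position pos;
# returns 0-based end (exclusive) of the first (= greedy/longest-repeat)
# successful match, or -1
matchFrom <- function(v, pos, elements, k, anchorC) {
  if (k > length(elements)) {
    if (anchorC && pos != length(v)) return(-1L)
    return(pos)
  }
  el <- elements[[k]]
  # how many copies of this element can match greedily?
  maxRep <- el$lo
  while (maxRep < el$hi && pos + maxRep < length(v) &&
         v[pos + maxRep + 1L] %in% el$allowed)
    maxRep <- maxRep + 1L
  for (rep in seq(maxRep, el$lo)) {
    if (pos + rep > length(v)) next
    if (rep > 0L && !all(v[(pos + 1L):(pos + rep)] %in% el$allowed)) next
    r <- matchFrom(v, pos + rep, elements, k + 1L, anchorC)
    if (r >= 0L) return(r)
  }
  -1L
}

#' Scan a protein with a PROSITE-style pattern
#'
#' Reports, for every start position at which the pattern matches, the
#' greedy (longest-repeat-first) match — the same semantics as the
#' equivalent regular expression with greedy quantifiers. Matches may
#' overlap and are returned in ascending start order.
#'
#' @param pattern A pattern string or a [parseProsite()] result.
#' @param seq Protein sequence (string, `AAString`, or single-record
#'   `AAStringSet`).
#' @return Integer matrix with columns `start`, `end`: 0-based half-open
#'   coordinates of each match.
#' @examples
#' scanPattern("C-x(3)-C", "CAAAC")   # one match spanning the whole string
#' @export
scanPattern <- function(pattern, seq) {
  if (!inherits(pattern, "prositePattern")) pattern <- parseProsite(pattern)
  s <- if (inherits(seq, "AAStringSet")) as.character(seq[[1L]])
       else as.character(seq)
  if (!nzchar(s)) stop("empty sequence")
  checkProtein(s, "scan target")
  v <- chars(s)
  starts <- if (pattern$anchorN) 0L else 0:(length(v) - 1L)
  el1 <- pattern$elements[[1L]]
  if (el1$lo >= 1L)   # cheap prefilter: first residue must fit element 1
    starts <- starts[v[starts + 1L] %in% el1$allowed]
  if (!length(starts))
    return(matrix(integer(), 0L, 2L,
                  dimnames = list(NULL, c("start", "end"))))
  hits <- lapply(starts, function(st) {
    e <- matchFrom(v, st, pattern$elements, 1L, pattern$anchorC)
    if (e >= 0L) c(start = st, end = e) else NULL
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  out <- if (length(hits)) do.call(rbind, hits)
         else matrix(integer(), 0L, 2L)
  colnames(out) <- c("start", "end")
  out
}
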