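# Independent oracles used across the suite. Each is coded from first
# principles (different algorithm/data source than the implementation it
# checks).

AAPOOL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")

randPeptide <- function(n) paste(sample(AAPOOL, n, replace = TRUE),
                                 collapse = "")

# ---- affine-gap alignment scores by three-state dynamic programming ----
# (gap run of length L costs open + L * ext)
.b62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

gotohScore <- function(q, t, open = 11, ext = 1, local = FALSE,
                       mat = .b62) {
  a <- strsplit(q, "")[[1]]
  b <- strsplit(t, "")[[1]]
  n <- length(a)
  m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (!local) {
    for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  } else {
    M[, 1] <- 0
    M[1, ] <- 0
  }
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- mat[a[i - 1], b[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
    if (local) M[i, j] <- max(M[i, j], s, 0)
    Ix[i, j] <- max(M[i - 1, j] - (open + ext), Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - (open + ext), Iy[i, j - 1] - ext)
    if (local) best <- max(best, M[i, j])
  }
  if (local) best else max(M[n + 1, m + 1], Ix[n + 1, m + 1],
                           Iy[n + 1, m + 1])
}

# ---- six-frame ORF enumeration via Biostrings translation ----
oracleOrfs <- function(nt, minAa) {
  L <- nchar(nt)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") nt else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    for (off in 0:2) {
      nCod <- (L - off) %/% 3
      if (nCod < 1) next
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, off + 1, off + 3 * nCod)),
        if.fuzzy.codon = "X", no.init.codon = TRUE)))
      segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
      for (seg in segs) {
        if (nchar(seg) >= minAa)
          out[[length(out) + 1]] <- c(seq = seg, variant = "open",
                                      strand = strand)
        mpos <- regexpr("M", seg, fixed = TRUE)
        if (mpos > 1) {
          pep <- substr(seg, mpos, nchar(seg))
          if (nchar(pep) >= minAa)
            out[[length(out) + 1]] <- c(seq = pep, variant = "atg",
                                        strand = strand)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(seq = character(), variant = character(),
                      strand = character()))
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$seq, df$variant), ]
}

# ---- PROSITE pattern -> PCRE translation, scanned per start position ----
prositeToRegex <- function(p) {
  p <- trimws(p)
  anchorN <- startsWith(p, "<")
  if (anchorN) p <- substr(p, 2, nchar(p))
  anchorC <- endsWith(p, ">")
  if (anchorC) p <- substr(p, 1, nchar(p) - 1)
  toks <- strsplit(p, "-", fixed = TRUE)[[1]]
  rx <- vapply(toks, function(tok) {
    m <- regmatches(tok, regexec(
      "^(x|[A-WYZ]|\\[[A-Z]+\\]|\\{[A-Z]+\\})(\\((\\d+)(,(\\d+))?\\))?$",
      tok))[[1]]
    base <- m[2]
    core <- if (base == "x") "[A-Z]"
      else if (startsWith(base, "[")) base
      else if (startsWith(base, "{"))
        paste0("[^", gsub("[{}]", "", base), "]")
      else base
    reps <- if (nzchar(m[6])) sprintf("{%s,%s}", m[4], m[6])
      else if (nzchar(m[4])) sprintf("{%s}", m[4])
      else ""
    paste0(core, reps)
  }, character(1))
  list(rx = paste(rx, collapse = ""), anchorN = anchorN, anchorC = anchorC)
}

oracleScan <- function(pattern, s) {
  tr <- prositeToRegex(pattern)
  rx <- paste0("^(?:", tr$rx, ")", if (tr$anchorC) "$" else "")
  L <- nchar(s)
  starts <- if (tr$anchorN) 0 else 0:(L - 1)
  hits <- lapply(starts, function(st) {
    m <- regexpr(rx, substr(s, st + 1, L), perl = TRUE)
    if (m == 1) c(start = st, end = st + attr(m, "match.length")) else NULL
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  out <- if (length(hits)) do.call(rbind, hits)
         else matrix(integer(), 0, 2)
  colnames(out) <- c("start", "end")
  out
}

randomProsite <- function() {
  nEl <- sample(2:5, 1)
  toks <- vapply(seq_len(nEl), function(i) {
    base <- switch(sample(4, 1),
      "x",
      sample(AAPOOL, 1),
      paste0("[", paste(sample(AAPOOL, sample(2:4, 1)), collapse = ""),
             "]"),
      paste0("{", paste(sample(AAPOOL, sample(1:3, 1)), collapse = ""),
             "}"))
    rep <- switch(sample(3, 1),
      "",
      sprintf("(%d)", sample(1:3, 1)),
      { lo <- sample(0:2, 1); sprintf("(%d,%d)", lo, lo + sample(1:2, 1)) })
    paste0(base, rep)
  }, character(1))
  paste(toks, collapse = "-")
}

# ---- residue masses from elemental composition (independent source) ----
.elements <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069)
.formulas <- list(  # residue formulas (C, H, N, O, S atom counts)
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))

oracleMass <- function(seq, cyclic = FALSE, nDisulfides = 0) {
  v <- strsplit(seq, "")[[1]]
  res <- sum(vapply(v, function(aa)
    sum(.formulas[[aa]] * .elements), numeric(1)))
  water <- 2 * .elements[["H"]] + .elements[["O"]]
  res + (!cyclic) * water - 2 * .elements[["H"]] * nDisulfides
}

# ---- additive distance matrices from random trees ----
randomAdditiveMatrix <- function(nTaxa) {
  tr <- ape::rtree(nTaxa, br = function(n) stats::runif(n, 0.1, 1))
  d <- ape::cophenetic.phylo(tr)
  d[order(rownames(d)), order(colnames(d))]
}

# path-length (cophenetic) matrix of an unrooted phylo tree
treePathMatrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d))]
}

# small helper: build a CyclotideDomain from a mature string
domainFromMature <- function(id, mature, refLoops = topologyReferences()) {
  ann <- parseArchitecture(mature, id = id)
  classifyTopology(extractLoops(ann, mature), refLoops)
}

# random (or fixed-part) test mature domain over the canonical framework;
# defaults avoid Pro in loop 5 and Asn/Asp in loop 6 so topology and
# cyclization are controlled by the explicit arguments
buildTestMature <- function(pre = NULL, l1 = NULL, l2 = NULL, l3 = NULL,
                            l4 = NULL, l5 = NULL, l6 = NULL, cyc = "N") {
  noC <- setdiff(AAPOOL, "C")
  rnd <- function(n, pool) paste(sample(pool, n, TRUE), collapse = "")
  if (is.null(pre)) pre <- paste0("G", rnd(sample(0:2, 1),
                                           setdiff(noC, "T")))
  if (is.null(l1)) l1 <- paste0("E", rnd(2, noC))
  if (is.null(l2)) l2 <- rnd(4, noC)
  if (is.null(l3)) l3 <- rnd(sample(4:8, 1), noC)
  if (is.null(l4)) l4 <- rnd(1, noC)
  if (is.null(l5)) l5 <- rnd(4, setdiff(noC, "P"))
  if (is.null(l6)) l6 <- rnd(sample(5:8, 1), setdiff(noC, c("N", "D")))
  paste0(pre, "C", l1, "C", l2, "C", l3, "C", l4, "C", l5, "C", l6, cyc)
}
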