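# Ground-truthed synthetic data: albumin-1-type precursor transcripts with
# known region boundaries and topologies, decoy ORFs, MALDI peak lists and
# tissue-clustered TPM matrices. All generators take an explicit seed and
# are deterministic given it.

TISSUES <- c("leaf", "flower", "pod", "stem")

defaultTissueMeans <- function() {
  matrix(c(20, 10, 200, 150,      # pod/stem-high (Bracelet-like profile)
           180, 15, 30, 25,       # leaf-high (Moebius-like profile)
           25, 120, 20, 30),      # flower-high
         nrow = 3L, byrow = TRUE,
         dimnames = list(NULL, TISSUES))
}

#' Simulation configuration
#'
#' Defaults mirror the observed composition of a Fabaceae cyclotide
#' transcriptome survey: topology proportions from the 51-domain tally
#' (11 Moebius / 27 Bracelet / 8 Hybrid / 3 acyclic / 2 unusual), a
#' truncation probability of 9/71 partial transcripts, and three planted
#' expression clusters over four tissues.
#'
#' @param nCyclotide,nDecoy Numbers of true precursors and decoys.
#' @param topologyMix Named proportions over
#'   `mobius`/`bracelet`/`hybrid`/`acyclic`/`unusual` (must sum to 1).
#' @param truncationProb Probability that a precursor loses its 5' and/or
#'   3' regions (applied independently per end).
#' @param loopRanges List of loop-length ranges (see defaults).
#' @param peakNoiseSd Gaussian m/z noise, Da.
#' @param peakFraction Fraction of domains emitted into the peak list.
#' @param decoyPeakCount Number of uniform decoy peaks.
#' @param expressionK,nGenes,tissueMeans,sdLog Planted expression-cluster
#'   spec: number of clusters, genes, per-cluster tissue means (k x 4
#'   matrix) and log-normal dispersion.
#' @param seed Integer seed (mandatory).
#' @return Validated config list of class `"simConfig"`.
#' @export
simConfig <- function(nCyclotide = 40L, nDecoy = 60L,
                      topologyMix = c(mobius = 0.216, bracelet = 0.529,
                                      hybrid = 0.157, acyclic = 0.059,
                                      unusual = 0.039),
                      truncationProb = 0.125,
                      loopRanges = list(loop1 = c(3L, 3L),
                                        loop2 = c(4L, 4L),
                                        loop3_mobius = c(4L, 5L),
                                        loop3_bracelet = c(6L, 8L),
                                        loop4 = c(1L, 1L),
                                        loop5 = c(4L, 5L),
                                        loop6 = c(5L, 8L)),
                      peakNoiseSd = 0.1, peakFraction = 0.6,
                      decoyPeakCount = 10L, expressionK = 3L,
                      nGenes = 51L, tissueMeans = defaultTissueMeans(),
                      sdLog = 0.25, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (nCyclotide < 0L || nDecoy < 0L) stop("counts must be >= 0")
  if (abs(sum(topologyMix) - 1) > 1e-8)
    stop("topology proportions must sum to 1")
  if (any(topologyMix < 0)) stop("negative topology proportion")
  if (truncationProb < 0 || truncationProb > 1)
    stop("truncationProb must be in [0, 1]")
  if (peakNoiseSd < 0) stop("peakNoiseSd must be >= 0")
  if (expressionK < 1L) stop("expressionK must be >= 1")
  if (nrow(tissueMeans) < expressionK)
    stop("tissueMeans needs one row per cluster")
  if (any(tissueMeans <= 0)) stop("tissue means must be positive")
  if (any(apply(tissueMeans[seq_len(expressionK), , drop = FALSE], 1L,
                stats::var) == 0))
    stop("zero-variance cluster profile: tissue means constant")
  structure(list(nCyclotide = as.integer(nCyclotide),
                 nDecoy = as.integer(nDecoy), topologyMix = topologyMix,
                 truncationProb = truncationProb, loopRanges = loopRanges,
                 peakNoiseSd = peakNoiseSd, peakFraction = peakFraction,
                 decoyPeakCount = as.integer(decoyPeakCount),
                 expressionK = as.integer(expressionK),
                 nGenes = as.integer(nGenes), tissueMeans = tissueMeans,
                 sdLog = sdLog, seed = as.integer(seed)),
            class = "simConfig")
}

# residue pools (mature domains keep cysteines to the framework; the
# cyclization window and pre-Cys flank stay free of confounding residues)
POOL_NOC <- setdiff(AA20, "C")
POOL_LOOP6 <- setdiff(AA20, c("C", "N", "D"))
POOL_PRE <- setdiff(AA20, c("C", "T"))
POOL_HYDRO <- c("L", "V", "A", "I", "F", "W")

rndStr <- function(n, pool) paste(sample(pool, n, replace = TRUE),
                                  collapse = "")

mutateStr <- function(s, nMut, positions, pool) {
  if (nMut < 1L || !length(positions)) return(s)
  pos <- sample(positions, min(nMut, length(positions)))
  for (p in pos) substr(s, p, p) <- sample(pool, 1L)
  s
}

rangeDraw <- function(r) if (r[1L] == r[2L]) r[1L] else
  sample(r[1L]:r[2L], 1L)

# largest-remainder allocation of n items to the mix proportions, so every
# class with non-negligible weight is represented at realistic n
allocateCounts <- function(mix, n) {
  raw <- mix * n
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0L) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(left)]
    cnt[extra] <- cnt[extra] + 1L
  }
  as.integer(cnt)
}

# draw a mature domain for a topology; returns list(mature, cyc, topology)
drawMature <- function(topology, lr) {
  tpl <- topologyReferences()
  fam <- if (topology %in% c("mobius", "hybrid")) "mobius" else "bracelet"
  pre <- paste0("G", rndStr(sample(0:3, 1L), POOL_PRE))
  l1 <- paste0("E", rndStr(rangeDraw(lr$loop1) - 1L, POOL_NOC))
  l2 <- mutateStr(tpl$loop2[tpl$label == fam], 1L,
                  seq_len(nchar(tpl$loop2[tpl$label == fam])), POOL_NOC)
  l3base <- tpl$loop3[tpl$label == fam]
  l3len <- rangeDraw(if (fam == "mobius") lr$loop3_mobius
                     else lr$loop3_bracelet)
  l3 <- if (l3len > nchar(l3base))
    paste0(l3base, rndStr(l3len - nchar(l3base), POOL_NOC))
  else substr(l3base, 1L, l3len)
  l3 <- mutateStr(l3, 1L, seq_len(min(4L, nchar(l3))), POOL_NOC)
  l4 <- rndStr(rangeDraw(lr$loop4), POOL_NOC)
  l5len <- rangeDraw(lr$loop5)
  l5 <- if (topology == "mobius") {
    s <- rndStr(l5len, setdiff(POOL_NOC, "P"))
    at <- sample(l5len, 1L)
    substr(s, at, at) <- "P"
    s
  } else rndStr(l5len, setdiff(POOL_NOC, "P"))
  l6 <- rndStr(rangeDraw(lr$loop6), POOL_LOOP6)
  cyc <- if (topology == "acyclic") ""
         else sample(c("N", "D"), 1L, prob = c(0.9, 0.1))
  mature <- paste0(pre, "C", l1, "C", l2, "C", l3, "C", l4, "C", l5, "C",
                   l6, cyc)
  if (topology == "unusual") {
    if (stats::runif(1) < 0.5) {
      # extra cysteine in loop 1 (7-Cys framework)
      at <- nchar(pre) + 1L + sample(nchar(l1), 1L)
      mature <- paste0(substr(mature, 1L, at), "C",
                       substr(mature, at + 1L, nchar(mature)))
    } else {
      # lose Cys IV (5-Cys framework)
      cp <- charPositions(mature, "C")
      substr(mature, cp[4L], cp[4L]) <- "S"
    }
  }
  list(mature = mature, cyc = cyc)
}

aaToCodons <- local({
  split(names(CODON_TABLE), CODON_TABLE)
})

encodeProtein <- function(p) {
  v <- chars(p)
  paste(vapply(v, function(aa) sample(aaToCodons[[aa]], 1L), character(1)),
        collapse = "")
}

makeTranscript <- function(protein) {
  utr5 <- paste0(if ((k <- sample(0:6, 1L)) > 0L)
    rndStr(3L * k, c("A", "C", "G", "T")) else "", "TAA")
  utr3 <- paste0("TAA", rndStr(3L * sample(0:6, 1L), c("A", "C", "G", "T")))
  paste0(utr5, encodeProtein(protein), utr3)
}

# encode a protein, resampling synonymous codons until no *other* reading
# frame yields a cysteine-windowed ORF (mineable collisions are rejected,
# so the encoded protein is the transcript's only mineable product)
cleanTranscript <- function(protein, minAa = 50L) {
  for (try in 1:50) {
    nt <- makeTranscript(protein)
    orfs <- findOrfs(nt, minAa = minAa, id = "tmp")
    sp <- as.character(orfs)
    spurious <- sp[sp != protein]
    if (!any(vapply(spurious, hasCysWindow, logical(1)))) return(nt)
  }
  stop("could not encode transcript without spurious cysteine-rich ORFs")
}

# a decoy evades mining iff it lacks a >=5-Cys/40-aa window: curation
# requires the window of every candidate, and the six-cysteine framework
# patterns cannot match without one
decoyEvades <- function(s, patterns) {
  !hasCysWindow(s)
}

#' Generate a ground-truthed precursor transcript set
#'
#' Each true precursor encodes the albumin-1 architecture: an ER signal
#' peptide (Met + hydrophobic core) ending in TEA, a mature six-cysteine
#' domain with topology-consistent loops (loop-5 Pro for Moebius;
#' Bracelet-range loop 3 for Bracelet; Moebius-like loops 2-3 without the
#' loop-5 Pro for Hybrid; no C-terminal Asn/Asp for acyclic; 5 or 7
#' cysteines for unusual), a ~10-aa linker, a ~50-aa albumin-1a chain and
#' a short C-terminal propeptide. Decoys are albumin-1-like proteins
#' without a cyclotide domain, random ORFs, and shuffled cyclotides, all
#' resampled until they evade the mining criteria. Truncation removes the
#' 5' and/or 3' regions with the configured probability.
#'
#' @param cfg A [simConfig()].
#' @return List: `transcripts` (`DNAStringSet` with a `tissue` metadata
#'   column) and `truth` (`data.frame`: per-transcript protein, region
#'   boundaries (1-based on the protein, `NA` when absent), topology,
#'   mature sequence, cyclization residue, `lost_5p`/`lost_3p`/`is_decoy`
#'   flags and decoy type).
#' @export
generatePrecursorSet <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  patterns <- cyclotidePatterns()
  lr <- cfg$loopRanges
  withSeed(cfg$seed, {
    rows <- list()
    seqs <- character()
    topoDraw <- if (cfg$nCyclotide)
      sample(rep(names(cfg$topologyMix),
                 allocateCounts(cfg$topologyMix, cfg$nCyclotide)))
    else character()
    for (i in seq_len(cfg$nCyclotide)) {
      topo <- topoDraw[i]
      dm <- drawMature(topo, lr)
      signal <- paste0("M", rndStr(15L, POOL_HYDRO), "TEA")
      linker <- mutateStr(linkerConsensus(), 2L, 2:9, POOL_LOOP6)
      alb <- mutateStr(alb1aConsensus(), 5L, 4:47, POOL_NOC)
      ctpp <- rndStr(sample(6:10, 1L), POOL_NOC)
      lost5 <- stats::runif(1) < cfg$truncationProb
      lost3 <- stats::runif(1) < cfg$truncationProb
      parts <- c(if (!lost5) signal, dm$mature, linker,
                 if (!lost3) c(alb, ctpp))
      protein <- paste(parts, collapse = "")
      # 1-based regions on the (possibly truncated) protein
      off <- 0L
      reg <- rep(NA_integer_, 10L)
      names(reg) <- as.vector(t(outer(REGION_NAMES, c("start", "end"),
                                      paste, sep = "_")))
      if (!lost5) {
        reg["signal_start"] <- 1L
        reg["signal_end"] <- nchar(signal)
        off <- nchar(signal)
      }
      reg["mature_start"] <- off + 1L
      reg["mature_end"] <- off + nchar(dm$mature)
      off <- off + nchar(dm$mature)
      reg["linker_start"] <- off + 1L
      reg["linker_end"] <- off + nchar(linker)
      off <- off + nchar(linker)
      if (!lost3) {
        reg["albumin1a_start"] <- off + 1L
        reg["albumin1a_end"] <- off + nchar(alb)
        off <- off + nchar(alb)
        reg["ctpp_start"] <- off + 1L
        reg["ctpp_end"] <- off + nchar(ctpp)
      }
      id <- sprintf("syn_cyc_%03d", i)
      rows[[length(rows) + 1L]] <- c(
        list(id = id, is_decoy = FALSE, decoy_type = NA_character_,
             topology = topo, mature = dm$mature, cyclization = dm$cyc,
             lost_5p = lost5, lost_3p = lost3, protein = protein),
        as.list(reg))
      seqs[id] <- cleanTranscript(protein)
    }
    decoyTypes <- if (cfg$nDecoy)
      rep_len(c("albumin_like", "random_orf", "shuffled"), cfg$nDecoy)
    else character()
    for (i in seq_len(cfg$nDecoy)) {
      type <- decoyTypes[i]
      protein <- NULL
      for (try in 1:100) {
        cand <- switch(type,
          albumin_like = paste0("M", rndStr(15L, POOL_HYDRO), "TEA",
                                mutateStr(linkerConsensus(), 2L, 2:9,
                                          POOL_LOOP6),
                                mutateStr(alb1aConsensus(), 5L, 4:47,
                                          POOL_NOC),
                                rndStr(sample(6:10, 1L), POOL_NOC)),
          random_orf = rndStr(sample(60:150, 1L), AA20),
          shuffled = paste(sample(chars(paste0(
            "M", rndStr(15L, POOL_HYDRO), "TEA",
            drawMature(sample(c("mobius", "bracelet"), 1L), lr)$mature,
            linkerConsensus(), alb1aConsensus()))), collapse = ""))
        if (decoyEvades(cand, patterns)) {
          protein <- cand
          break
        }
      }
      if (is.null(protein))
        stop("could not generate an evading decoy of type ", type)
      id <- sprintf("syn_dec_%03d", i)
      rows[[length(rows) + 1L]] <- c(
        list(id = id, is_decoy = TRUE, decoy_type = type,
             topology = NA_character_, mature = NA_character_,
             cyclization = NA_character_, lost_5p = NA, lost_3p = NA,
             protein = protein),
        as.list(stats::setNames(rep(NA_integer_, 10L),
                                as.vector(t(outer(REGION_NAMES,
                                                  c("start", "end"),
                                                  paste, sep = "_"))))))
      seqs[id] <- cleanTranscript(protein)
    }
    truth <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    names(truth)[10:19] <- as.vector(t(outer(
      REGION_NAMES, c("start", "end"), paste, sep = "_")))
    transcripts <- Biostrings::DNAStringSet(seqs)
    S4Vectors::mcols(transcripts) <- S4Vectors::DataFrame(
      tissue = sample(TISSUES, length(seqs), replace = TRUE))
    list(transcripts = transcripts, truth = truth)
  })
}

#' Generate a synthetic MALDI peak list from cyclotide domains
#'
#' A sampled subset of the domains is emitted as \[M+H\]+ of the fully
#' oxidized cyclic (linear for acyclic) monoisotopic mass, plus Gaussian
#' noise; uniform decoy peaks are added. Deterministic given the config
#' seed.
#'
#' @param domains List of [CyclotideDomain-class] objects.
#' @param cfg A [simConfig()].
#' @return List: `peakList` (a [PeakList-class]) and `truth`
#'   (`data.frame`: `peak`, `domain_id`, `predicted`).
#' @export
generatePeakList <- function(domains, cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  withSeed(subSeed(cfg$seed, 2L), {
    truth <- data.frame(peak = numeric(), domain_id = character(),
                        predicted = numeric())
    mz <- numeric()
    if (length(domains)) {
      recs <- domainMassRecords(domains)
      nPick <- max(1L, round(cfg$peakFraction * nrow(recs)))
      pick <- sort(sample.int(nrow(recs), min(nPick, nrow(recs))))
      obs <- recs$mh[pick] + stats::rnorm(length(pick), 0, cfg$peakNoiseSd)
      truth <- data.frame(peak = obs, domain_id = recs$id[pick],
                          predicted = recs$mh[pick])
      mz <- obs
    }
    if (cfg$decoyPeakCount > 0L) {
      lo <- if (length(mz)) min(mz) - 300 else 2500
      hi <- if (length(mz)) max(mz) + 300 else 3800
      mz <- c(mz, stats::runif(cfg$decoyPeakCount, lo, hi))
    }
    list(peakList = PeakList(mz, label = "synthetic"), truth = truth)
  })
}

#' Generate a planted-cluster TPM matrix
#'
#' Genes are assigned to `expressionK` clusters; genes in a cluster share
#' the cluster's tissue-mean profile with multiplicative log-normal noise.
#' Deterministic given the config seed.
#'
#' @param cfg A [simConfig()].
#' @return List: `tpm` (genes x tissues matrix) and `labels` (integer
#'   cluster assignment per gene).
#' @export
generateExpression <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  withSeed(subSeed(cfg$seed, 3L), {
    k <- cfg$expressionK
    mu <- cfg$tissueMeans[seq_len(k), , drop = FALSE]
    labels <- rep_len(seq_len(k), cfg$nGenes)
    tpm <- t(vapply(seq_len(cfg$nGenes), function(g)
      exp(log(mu[labels[g], ]) + stats::rnorm(ncol(mu), 0, cfg$sdLog)),
      numeric(ncol(mu))))
    rownames(tpm) <- sprintf("gene_%03d", seq_len(cfg$nGenes))
    colnames(tpm) <- colnames(mu)
    names(labels) <- rownames(tpm)
    list(tpm = tpm, labels = labels)
  })
}
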