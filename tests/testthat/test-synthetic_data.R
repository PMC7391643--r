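test_that("config validation rejects infeasible settings", {
  expect_error(simConfig(seed = 1, topologyMix = c(mobius = 0.5,
                                                   bracelet = 0.4,
                                                   hybrid = 0, acyclic = 0,
                                                   unusual = 0)),
               "sum to 1")
  expect_error(simConfig(), "mandatory")
  expect_error(simConfig(seed = 1, nCyclotide = -1), ">= 0")
  expect_error(simConfig(seed = 1,
                         tissueMeans = matrix(5, 3, 4,
                                              dimnames = list(NULL,
                                                cyclomine:::TISSUES))),
               "zero-variance")
})

test_that("generation is deterministic and respects flags", {
  cfg <- simConfig(nCyclotide = 5, nDecoy = 6, truncationProb = 0,
                   seed = 11)
  g1 <- generatePrecursorSet(cfg)
  g2 <- generatePrecursorSet(cfg)
  expect_identical(as.character(g1$transcripts),
                   as.character(g2$transcripts))
  expect_identical(g1$truth, g2$truth)
  expect_false(any(g1$truth$lost_5p[!g1$truth$is_decoy]))
  expect_false(any(g1$truth$lost_3p[!g1$truth$is_decoy]))

  g3 <- generatePrecursorSet(simConfig(nCyclotide = 0, nDecoy = 5,
                                       seed = 11))
  expect_identical(nrow(g3$truth), 5L)
  expect_true(all(g3$truth$is_decoy))
})

test_that("non-decoy matures carry the designed cysteine count", {
  cfg <- simConfig(nCyclotide = 12, nDecoy = 0, truncationProb = 0,
                   seed = 21)
  g <- generatePrecursorSet(cfg)
  for (i in seq_len(nrow(g$truth))) {
    nC <- sum(strsplit(g$truth$mature[i], "")[[1]] == "C")
    if (g$truth$topology[i] == "unusual") expect_true(nC %in% c(5, 7))
    else expect_identical(nC, 6L)
    # cysteines live only in the mature domain
    prot <- g$truth$protein[i]
    outside <- paste0(substr(prot, 1, g$truth$mature_start[i] - 1),
                      substr(prot, g$truth$mature_end[i] + 1, nchar(prot)))
    expect_false(grepl("C", outside, fixed = TRUE))
  }
})

test_that("decoy proteins never contain a mineable cysteine window", {
  g <- generatePrecursorSet(simConfig(nCyclotide = 0, nDecoy = 30,
                                      seed = 31))
  for (p in g$truth$protein) {
    expect_false(cyclomine:::hasCysWindow(p))
    for (pat in cyclotidePatterns())
      expect_identical(nrow(scanPattern(pat, p)), 0L)
  }
})

test_that("noiseless peak lists are matched back to their domains exactly", {
  cfg <- simConfig(nCyclotide = 8, nDecoy = 0, truncationProb = 0,
                   peakNoiseSd = 0, decoyPeakCount = 0, peakFraction = 1,
                   seed = 41)
  g <- generatePrecursorSet(cfg)
  doms <- lapply(seq_len(nrow(g$truth)), function(i)
    domainFromMature(g$truth$id[i], g$truth$mature[i]))
  pk <- generatePeakList(doms, cfg)
  expect_identical(nrow(pk$truth), 8L)
  m <- matchPeaks(domainMassRecords(doms), pk$peakList, tol = 0.1)
  got <- m$id[match(pk$truth$peak, m$peak)]
  expect_identical(got, pk$truth$domain_id)
  # reproducible given the seed
  pk2 <- generatePeakList(doms, cfg)
  expect_identical(pk$truth, pk2$truth)
  # empty domains with zero decoy peaks -> empty list, not an error
  empty <- generatePeakList(list(), cfg)
  expect_length(peaks(empty$peakList), 0)
})

test_that("planted expression clusters have the declared structure", {
  cfg <- simConfig(seed = 51, expressionK = 1, nGenes = 10)
  e1 <- generateExpression(cfg)
  expect_identical(unname(unique(e1$labels)), 1L)
  cfg3 <- simConfig(seed = 51, expressionK = 3, nGenes = 30)
  e3 <- generateExpression(cfg3)
  expect_identical(sort(unname(unique(e3$labels))), 1:3)
  expect_true(all(e3$tpm > 0))
  e3b <- generateExpression(cfg3)
  expect_identical(e3$tpm, e3b$tpm)
})
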