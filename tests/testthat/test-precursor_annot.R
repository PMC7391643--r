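makePrecursor <- function(mature,
                          signal = paste0("M", strrep("L", 15), "TEA"),
                          linker = linkerConsensus(),
                          alb = alb1aConsensus(), ctpp = "QSFLKR") {
  paste0(signal, mature, linker, alb, ctpp)
}

test_that("constructed precursors parse to their exact regions", {
  mature <- buildTestMature()
  p <- makePrecursor(mature)
  ann <- parseArchitecture(p, id = "t")
  r <- regions(ann)
  expect_identical(unname(r["signal", ]), c(1L, 19L))
  expect_identical(unname(r["mature", ]), c(20L, 19L + nchar(mature)))
  expect_identical(unname(r["linker", ]),
                   c(20L + nchar(mature), 29L + nchar(mature)))
  expect_identical(unname(r["albumin1a", ]),
                   c(30L + nchar(mature), 79L + nchar(mature)))
  expect_identical(unname(r["ctpp", "end"]), nchar(p))
  expect_identical(ann@cleavageMotif, "TEA")
  expect_true(all(completeness(ann)))
})

test_that("signal-less precursors parse with has5p = FALSE", {
  mature <- buildTestMature()
  p <- paste0(mature, linkerConsensus(), alb1aConsensus(), "QSFLKR")
  ann <- parseArchitecture(p, id = "t")
  expect_false(completeness(ann)[["has5p"]])
  expect_identical(unname(regions(ann)["mature", ]),
                   c(1L, nchar(mature)))
})

test_that("proteins without a cysteine cluster are rejected", {
  expect_error(parseArchitecture(strrep("A", 80), id = "t"),
               "not a cyclotide precursor")
})

test_that("loop decomposition reconstructs the mature domain", {
  # spacer-style mature with known loops
  mature <- "GECAAACDDCBDCEECFFCGGGGGN"
  d <- extractLoops(parseArchitecture(mature, id = "t"), mature)
  expect_identical(loops(d),
                   c("AAA", "DD", "BD", "EE", "FF", "GGGGGNGE"))
  expect_identical(cyclizationResidue(d), "N")
  # reconstruction invariant on random 6-Cys domains
  set.seed(55)
  for (k in 1:20) {
    m <- buildTestMature()
    dd <- extractLoops(parseArchitecture(m, id = "r"), m)
    expect_true(validObject(dd))
    cp <- cysPositions(dd)
    expect_length(cp, 6)
    post <- substr(matureSeq(dd), cp[6] + 1, nchar(matureSeq(dd)))
    pre <- substr(matureSeq(dd), 1, cp[1] - 1)
    expect_identical(loops(dd)[6], paste0(post, pre))
  }
})

test_that("atypical cysteine frameworks are flagged unusual", {
  m7 <- "GECACAACDDCBDCEECFFCGGGGGN"   # extra Cys in loop 1
  d <- extractLoops(parseArchitecture(m7, id = "t"), m7)
  expect_identical(topology(d), "unusual")
  expect_length(cysPositions(d), 7)
})

test_that("topology rules follow the stated decision order", {
  refs <- topologyReferences()
  # loop-5 Pro with C-terminal Asn -> mobius
  m <- buildTestMature(l5 = "TIPA")
  d <- classifyTopology(extractLoops(parseArchitecture(m, id = "m"), m),
                        refs)
  expect_identical(topology(d), "mobius")
  # missing cyclization residue -> acyclic
  m <- buildTestMature(cyc = "")
  d <- classifyTopology(extractLoops(parseArchitecture(m, id = "a"), m),
                        refs)
  expect_identical(topology(d), "acyclic")
  # Bracelet-template loops, no loop-5 Pro -> bracelet
  m <- buildTestMature(l2 = "VWIS", l3 = "SIFKGL", l5 = "TLVA")
  d <- classifyTopology(extractLoops(parseArchitecture(m, id = "b"), m),
                        refs)
  expect_identical(topology(d), "bracelet")
  # Moebius-template loops 2-3 without loop-5 Pro -> hybrid
  m <- buildTestMature(l2 = "GETY", l3 = "SGKY", l5 = "TLVA")
  d <- classifyTopology(extractLoops(parseArchitecture(m, id = "h"), m),
                        refs)
  expect_identical(topology(d), "hybrid")
  # no references, no Pro -> unclassified
  d <- classifyTopology(extractLoops(parseArchitecture(m, id = "u"), m),
                        refLoops = NULL)
  expect_identical(topology(d), "unclassified")
})

test_that("classification is deterministic and total", {
  set.seed(99)
  for (k in 1:10) {
    m <- buildTestMature()
    d1 <- classifyTopology(extractLoops(parseArchitecture(m, id = "x"), m))
    d2 <- classifyTopology(extractLoops(parseArchitecture(m, id = "x"), m))
    expect_identical(topology(d1), topology(d2))
    expect_true(topology(d1) %in% cyclomine:::TOPOLOGIES)
  }
})
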