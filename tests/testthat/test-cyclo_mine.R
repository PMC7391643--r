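test_that("mining recovers exactly the true precursors on synthetic data", {
  cfg <- simConfig(nCyclotide = 10, nDecoy = 20, truncationProb = 0,
                   seed = 101)
  gen <- generatePrecursorSet(cfg)
  orfs <- findOrfsSet(gen$transcripts)
  open <- orfs[S4Vectors::mcols(orfs)$variant == "open"]
  cands <- mineCyclotides(open, refs = referenceCyclotides())
  src <- S4Vectors::mcols(cands)$source_id
  trueIds <- gen$truth$id[!gen$truth$is_decoy]
  expect_setequal(src, trueIds)
})

test_that("refs-only mining returns an ORF identical to the reference", {
  ref <- Biostrings::AAStringSet(c(refA = buildTestMature()))
  orfs <- Biostrings::AAStringSet(c(o1 = as.character(ref[[1]]),
                                    o2 = strrep("A", 60)))
  S4Vectors::mcols(orfs) <- S4Vectors::DataFrame(
    source_id = c("t1", "t2"), frame = c(1L, 1L), start = c(0, 0),
    end = c(3 * 60, 3 * 60), variant = c("open", "open"))
  got <- mineCyclotides(orfs, patterns = NULL, refs = ref)
  expect_identical(names(got), "o1")
  expect_identical(S4Vectors::mcols(got)$provenance, "homology")
  # impossible thresholds with unrelated refs yield nothing
  ref2 <- Biostrings::AAStringSet(c(refB = strrep("W", 30)))
  expect_length(mineCyclotides(orfs, patterns = NULL, refs = ref2,
                               minIdentity = 100, minCoverage = 100), 0)
})

test_that("mining requires a pattern or a reference", {
  orfs <- Biostrings::AAStringSet(c(o = strrep("A", 60)))
  expect_error(mineCyclotides(orfs, patterns = NULL, refs = NULL),
               "at least one")
})

test_that("dedupe keeps unique precursors and domains with mapping", {
  set.seed(3)
  mat <- buildTestMature()
  p1 <- paste0("M", strrep("L", 15), "TEA", mat, linkerConsensus())
  p2 <- paste0("M", strrep("V", 15), "TEA", mat, linkerConsensus())
  precs <- Biostrings::AAStringSet(c(a = p1, b = p2, c = p1))
  doms <- list(domainFromMature("a", mat), domainFromMature("b", mat),
               domainFromMature("c", mat))
  dd <- dedupe(precs, doms)
  expect_length(dd$precursors, 2)   # p1 == p1 collapses
  expect_length(dd$domains, 1)      # same mature domain throughout
  expect_identical(unique(dd$mapping$domain_id), "a")
  # idempotence
  dd2 <- dedupe(dd$precursors, dd$domains)
  expect_length(dd2$precursors, 2)
  expect_length(dd2$domains, 1)
  # missing domains are retained as precursors with a warning
  expect_warning(dd3 <- dedupe(precs, list(doms[[1]], NULL, doms[[3]])),
                 "lack a parsed mature domain")
  expect_length(dd3$precursors, 2)
})

test_that("novelty flags honour exact and cyclic-rotation matches", {
  mat <- buildTestMature()
  refs <- Biostrings::AAStringSet(c(r1 = mat))
  S4Vectors::mcols(refs) <- S4Vectors::DataFrame(cyclic = TRUE)
  d <- domainFromMature("d", mat)
  expect_false(flagNovel(list(d), refs)[["d"]])
  # every rotation of a cyclic reference is non-novel
  n <- nchar(mat)
  for (off in c(3, 10, n - 2)) {
    rot <- paste0(substr(mat, off + 1, n), substr(mat, 1, off))
    # rotation oracle: explicit double-string containment
    expect_true(grepl(rot, paste0(mat, mat), fixed = TRUE))
    d2 <- new("CyclotideDomain", id = "rot", mature = rot,
              cysPositions = integer(), loops = character(),
              topology = "unclassified", cyclizationResidue = "N",
              loop1Glu = NA)
    expect_false(flagNovel(list(d2), refs)[["rot"]])
  }
  # acyclic query does not rotation-match a cyclic reference
  d3 <- new("CyclotideDomain", id = "ac",
            mature = paste0(substr(mat, 4, n), substr(mat, 1, 3)),
            cysPositions = integer(), loops = character(),
            topology = "acyclic", cyclizationResidue = "",
            loop1Glu = NA)
  expect_true(flagNovel(list(d3), refs)[["ac"]])
  # empty reference set: everything is novel
  expect_true(all(flagNovel(list(d), Biostrings::AAStringSet())))
})
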