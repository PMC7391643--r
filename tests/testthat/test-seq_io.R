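test_that("FASTA reading normalizes case, strips stops, rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "acgt"), f)
  r <- readFasta(f, "nt")
  expect_identical(names(r), "x")
  expect_identical(as.character(r[[1]]), "ACGT")

  writeLines(character(), f)
  expect_length(readFasta(f, "nt"), 0)

  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(readFasta(f, "nt"), "duplicate")

  writeLines(c(">p", "MKLV*"), f)
  expect_identical(as.character(readFasta(f, "aa")[[1]]), "MKLV")

  writeLines(c(">q", "MKJV"), f)
  expect_error(readFasta(f, "aa"), "illegal")
  writeLines(c("ACGT"), f)
  expect_error(readFasta(f, "nt"), "line 1")
})

test_that("FASTA writing wraps lines and round-trips arbitrary records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(character(), f)
  expect_length(readFasta(f, "aa"), 0)

  long <- setNames(paste(rep("A", 130), collapse = ""), "long")
  writeFasta(long, f, width = 60)
  lines <- readLines(f)
  expect_identical(nchar(lines[-1]), c(60L, 60L, 10L))

  set.seed(11)
  recs <- setNames(
    vapply(1:10, function(i) randPeptide(sample(1:200, 1)), character(1)),
    paste0("rec", 1:10))
  writeFasta(recs, f)
  back <- readFasta(f, "aa")
  expect_identical(as.character(back), recs)
})

test_that("ORF finder matches a brute-force six-frame enumerator", {
  set.seed(21)
  for (k in 1:10) {
    nt <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                collapse = "")
    got <- findOrfs(nt, minAa = 20, id = "t")
    gdf <- data.frame(seq = as.character(got),
                      variant = S4Vectors::mcols(got)$variant)
    gdf <- gdf[order(gdf$seq, gdf$variant), ]
    odf <- oracleOrfs(nt, 20)
    expect_identical(gdf$seq, odf$seq)
    expect_identical(gdf$variant, odf$variant)
  }
})

test_that("ORF coordinates translate back to the reported peptide", {
  set.seed(31)
  nt <- paste(sample(c("A", "C", "G", "T", "N"),  500,
                     replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
              collapse = "")
  orfs <- findOrfs(nt, minAa = 15, id = "t")
  m <- S4Vectors::mcols(orfs)
  for (i in seq_along(orfs)) {
    reg <- substr(nt, m$start[i] + 1, m$end[i])
    expect_identical((m$end[i] - m$start[i]) %% 3, 0)
    if (m$frame[i] < 0)
      reg <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(reg)))
    expect_identical(cyclomine:::translateNt(reg), as.character(orfs[[i]]))
  }
})

test_that("short transcripts and sub-threshold ORFs yield nothing", {
  expect_length(findOrfs("ATGGCT", minAa = 50, id = "t"), 0)
  # exactly one 49-aa ORF, below a 50-aa threshold
  set.seed(5)
  pep <- randPeptide(49)
  nt <- paste0("TAA", cyclomine:::encodeProtein(pep), "TAA")
  hits <- findOrfs(nt, minAa = 50, id = "t")
  expect_false(pep %in% as.character(hits))
  expect_true(pep %in% as.character(findOrfs(nt, minAa = 49, id = "t")))
})

test_that("peak lists load sorted/positive and reject bad cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("3072.4", "3110.4"), f)
  expect_equal(peaks(readPeakList(f)), c(3072.4, 3110.4))

  writeLines(c("3110.4", "3072.4"), f)
  expect_equal(peaks(readPeakList(f)), c(3072.4, 3110.4))

  writeLines(c("3072.4", "oops"), f)
  expect_error(readPeakList(f), "non-numeric")
  writeLines(c("-5"), f)
  expect_error(readPeakList(f), "positive")
})

test_that("expression tables validate shape, ids and values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tleaf\tpod", "g1\t1.5\t2", "g2\t0\t7"), f)
  m <- readExpression(f)
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(rownames(m), c("g1", "g2"))

  writeLines(c("gene\tleaf\tpod", "g1\t1.5\tNA"), f)
  expect_error(readExpression(f), "row g1")
  writeLines(c("gene\tleaf\tpod", "g1\t-1\t2"), f)
  expect_error(readExpression(f), "negative")
  writeLines(c("gene\tleaf\tpod", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(readExpression(f), "duplicate")
})
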