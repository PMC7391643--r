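test_that("cysteine-anchored alignment pads loops and round-trips", {
  m1 <- buildTestMature(pre = "G", l3 = "AAA")
  m2 <- buildTestMature(pre = "G", l3 = "AAAAA")
  d1 <- domainFromMature("d1", m1)
  d2 <- domainFromMature("d2", m2)
  a <- cysAnchorAlign(list(d1, d2))
  rows <- as.character(a)
  expect_identical(nchar(rows[["d1"]]), nchar(rows[["d2"]]))
  # identical domains align gap-free
  a2 <- cysAnchorAlign(list(d1, d1))
  expect_false(any(grepl("-", as.character(a2), fixed = TRUE)))
  # ungapping recovers the input mature sequences
  expect_identical(gsub("-", "", rows[["d1"]]), m1)
  expect_identical(gsub("-", "", rows[["d2"]]), m2)
  # shorter loop 3 is padded by the length difference
  expect_identical(nchar(gsub("[^-]", "", rows[["d1"]])) -
                     nchar(gsub("[^-]", "", rows[["d2"]])),
                   2L + (nchar(m2) - nchar(m1) - 2L))
})

test_that("non-canonical domains are excluded with a warning", {
  m7 <- "GECACAACDDCBDCEECFFCGGGGGN"
  d7 <- extractLoops(parseArchitecture(m7, id = "u"), m7)
  d6 <- domainFromMature("ok", buildTestMature())
  expect_warning(a <- cysAnchorAlign(list(d6, d7)), "excluded")
  expect_identical(names(a), "ok")
})

test_that("p-distance counts mismatches with pairwise deletion", {
  a <- c(x = "ACDEF", y = "ACDEF", z = "VWVWV")
  d <- pDistance(a)
  expect_equal(unname(d["x", "y"]), 0)
  expect_equal(unname(d["x", "z"]), 1)
  g <- c(x = "AC-EF", y = "ACD-F")
  dg <- pDistance(g)
  expect_equal(unname(dg["x", "y"]), 0)   # only columns 1,2,5 compared
  set.seed(91)
  rows <- vapply(1:6, function(i) {
    s <- strsplit(randPeptide(30), "")[[1]]
    s[sample(30, 4)] <- "-"
    paste(s, collapse = "")
  }, character(1))
  names(rows) <- paste0("s", 1:6)
  d <- pDistance(rows)
  m <- do.call(rbind, strsplit(rows, ""))
  for (i in 1:5) for (j in (i + 1):6) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    expect_equal(unname(d[i, j]), sum(m[i, ok] != m[j, ok]) / sum(ok))
  }
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  d <- matrix(c(0, 5, 9,
                5, 0, 10,
                9, 10, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  expect_identical(sort(tr$tip.label), c("A", "B", "C"))
  el <- setNames(tr$edge.length,
                 tr$tip.label[tr$edge[, 2]])
  # a = (dAB + dAC - dBC)/2, etc.
  expect_equal(unname(el["A"]), (5 + 9 - 10) / 2)
  expect_equal(unname(el["B"]), (5 + 10 - 9) / 2)
  expect_equal(unname(el["C"]), (9 + 10 - 5) / 2)
  expect_error(njTree(d[1:2, 1:2]), ">= 3")
})

test_that("NJ exactly recovers additive four-taxon trees", {
  # additive matrix for ((A,B),(C,D)) with internal branch 2
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  ext <- c(A = 1, B = 3, C = 2, D = 4)
  d["A", "B"] <- d["B", "A"] <- ext["A"] + ext["B"]
  d["C", "D"] <- d["D", "C"] <- ext["C"] + ext["D"]
  for (i in c("A", "B")) for (j in c("C", "D"))
    d[i, j] <- d[j, i] <- ext[i] + ext[j] + 2
  # four-point condition oracle: AB|CD is the valid split
  expect_lt(d["A", "B"] + d["C", "D"], d["A", "C"] + d["B", "D"])
  tr <- njTree(d)
  expect_equal(treePathMatrix(tr), d[order(rownames(d)),
                                     order(colnames(d))],
               tolerance = 1e-10)
})

test_that("newick output round-trips topology, lengths and supports", {
  set.seed(101)
  d <- randomAdditiveMatrix(6)
  tr <- njTree(d)
  tr$node.label <- as.character(c(100, 97, 88, 100)[seq_len(tr$Nnode)])
  f <- withr::local_tempfile(fileext = ".nwk")
  writeTreeNewick(tr, f)
  back <- ape::read.tree(f)
  expect_equal(treePathMatrix(back), treePathMatrix(tr), tolerance = 1e-9)
  # node numbering may differ after parsing; supports survive as a set
  expect_identical(sort(back$node.label), sort(tr$node.label))
})

test_that("bootstrap is seed-deterministic and supports clean clades", {
  m1 <- buildTestMature(pre = "G", l2 = "GETY", l3 = "SGKY")
  doms <- list(
    domainFromMature("a1", m1),
    domainFromMature("a2", sub("GETY", "GETF", m1)),
    domainFromMature("b1", buildTestMature(pre = "G", l2 = "VWIS",
                                           l3 = "SIFKGLAG",
                                           l6 = "WYWYWYW")),
    domainFromMature("b2", buildTestMature(pre = "G", l2 = "VWIS",
                                           l3 = "SIFKGWAG",
                                           l6 = "WYWYWYW")))
  a <- cysAnchorAlign(doms)
  t1 <- bootstrapTree(a, nReps = 200, seed = 5)
  t2 <- bootstrapTree(a, nReps = 200, seed = 5)
  expect_identical(t1$node.label, t2$node.label)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # the a1a2 | b1b2 bipartition should be near-unanimous
  expect_true(max(t1$node.label, na.rm = TRUE) >= 95)
})

test_that("identical sequences give a degenerate star-like result", {
  rows <- setNames(rep("ACDEFGHIK", 4), paste0("s", 1:4))
  tr <- bootstrapTree(rows, nReps = 20, seed = 3)
  expect_true(all(tr$edge.length == 0))
})
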