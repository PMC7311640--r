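test_that("identical sequences align gaplessly with full identity", {
  aln <- globalAlign(proteinRecord("a", "MKVH"), proteinRecord("b", "MKVH"))
  expect_identical(aln@aAligned, "MKVH")
  expect_identical(aln@bAligned, "MKVH")
  expect_equal(alignmentIdentity(aln), 1)
})

test_that("linear-gap toy alignment matches the closed-form optimum", {
  # match +1, mismatch -1, gap -2 per residue (gapOpen 0 = linear model)
  m <- matrix(-1L, 3, 3, dimnames = list(c("M", "K", "V"), c("M", "K", "V")))
  diag(m) <- 1L
  sch <- defaultScheme(matrix = m, gapOpen = 0L, gapExtend = -2L)
  aln <- globalAlign(proteinRecord("a", "MKV"), proteinRecord("b", "MV"), sch)
  expect_equal(aln@score, 0)
  expect_identical(aln@bAligned, "M-V")
  expect_equal(aln@score, bruteForceAlignScore("MKV", "MV", sch))
})

test_that("alignment score equals the exhaustive oracle on random pairs", {
  sch <- defaultScheme()
  set.seed(421)
  for (i in 1:40) {
    a <- randomProtein(sample(1:8, 1))
    b <- randomProtein(sample(1:8, 1))
    got <- globalAlign(proteinRecord("a", a), proteinRecord("b", b),
                       sch)@score
    expect_equal(got, bruteForceAlignScore(a, b, sch),
                 info = paste(a, "vs", b))
  }
})

test_that("substitution schemes are validated and NCBI matrices readable", {
  bad <- matrix(c(1L, 2L, 3L, 4L), 2, dimnames = list(c("A", "C"),
                                                      c("A", "C")))
  expect_error(defaultScheme(matrix = bad), "symmetric")
  expect_error(defaultScheme(gapExtend = 0L), "gapExtend")

  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# toy matrix", "   A  C", "A  4 -1", "C -1  5"), tf)
  m <- readSubstitutionMatrix(tf)
  expect_identical(m["A", "A"], 4L)
  expect_identical(m["A", "C"], -1L)
  expect_identical(m, t(m))
})

test_that("position maps follow the hand-constructed reference example", {
  # reference MKV aligned M-KV against query MAKV: 1,2,3 -> 1,3,4
  aln <- new("AlignedPair", aId = "ref", bId = "qry",
             aAligned = "M-KV", bAligned = "MAKV", score = 0)
  pm <- buildPositionMap(aln, referenceIsA = TRUE)
  expect_identical(pm@queryPos, c(1L, 3L, 4L))
  expect_identical(residuesAt("MAKV", pm, 1:3), c("M", "K", "V"))
})

test_that("gapless equal-length alignment gives the identity map", {
  aln <- globalAlign(proteinRecord("a", "MKVHW"), proteinRecord("b", "MKVHW"))
  pm <- buildPositionMap(aln)
  expect_identical(pm@queryPos, 1:5)
  expect_identical(residuesAt("MKVHW", pm, 2), "K")
})

test_that("reference positions aligned to query gaps read as GAP", {
  aln <- new("AlignedPair", aId = "ref", bId = "qry",
             aAligned = "MKV", bAligned = "M-V", score = 0)
  pm <- buildPositionMap(aln)
  expect_identical(residuesAt("MV", pm, 1:3), c("M", GAP, "V"))
})

test_that("out-of-range reference positions are a bounds error", {
  aln <- globalAlign(proteinRecord("a", "MKV"), proteinRecord("b", "MKV"))
  pm <- buildPositionMap(aln)
  expect_error(residuesAt("MKV", pm, 4), "out of range")
  expect_error(residuesAt("MKV", pm, 0), "out of range")
})

test_that("position maps are monotone-injective and recover planted residues", {
  sc <- makeReferenceScaffold(600, 3)
  for (s in 1:10) {
    cls <- if (s %% 2) "BF" else "nonBF"
    rec <- plantSequence(sc, cls, backgroundIdentity = 0.65,
                         indelRate = 0.005, seed = 100 + s)
    aln <- globalAlign(sc, rec)
    pm <- buildPositionMap(aln)                 # validity asserts monotone
    nz <- pm@queryPos[!is.na(pm@queryPos)]
    expect_true(all(diff(nz) > 0))
    truth <- attr(rec, "truth")
    expect_identical(residuesAt(rec, pm, c(232L, 234L, 367L)),
                     c(truth$res_232, truth$res_234, truth$res_367))
    expect_identical(paste(residuesAt(rec, pm, 427:431), collapse = ""),
                     truth$slbb)
  }
})

test_that("fingerprint read-off is invariant under terminal extensions", {
  sc <- makeReferenceScaffold(600, 3)
  rec <- plantSequence(sc, "BF", 0.7, seed = 77)
  base <- as.character(rec)[[1]]
  set.seed(78)
  for (i in 1:5) {
    nPad <- sample(1:50, 2)
    padded <- proteinRecord("pad", paste0(
      randomProtein(nPad[1]), base, randomProtein(nPad[2])))
    pm <- buildPositionMap(globalAlign(sc, padded))
    expect_identical(residuesAt(padded, pm, c(232L, 234L, 367L)),
                     residuesAt(rec, buildPositionMap(globalAlign(sc, rec)),
                                c(232L, 234L, 367L)))
  }
})
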