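test_that("default rules carry the published diagnostic residue sets", {
  rules <- defaultRules()
  expect_length(rules, 4L)
  r232 <- rules[[1]]
  expect_identical(r232@name, "nadh_site_232")
  expect_identical(r232@refPositions, 232L)
  expect_setequal(r232@bfAllowed, c("A", "E"))
  expect_setequal(r232@nonbfAllowed, c("T", "S"))
  r234 <- rules[[2]]
  expect_identical(r234@bfAllowed, "M")
  expect_setequal(r234@nonbfAllowed, c("K", "S", "A"))
  r367 <- rules[[3]]
  expect_identical(r367@refPositions, 367L)
  expect_identical(r367@bfAllowed, "F")
  expect_identical(r367@nonbfAllowed, "Y")
  slbb <- rules[[4]]
  expect_identical(slbb@refPositions, 427:431)
  expect_true(slbb@motif)
  expect_identical(slbb@bfAllowed, "GGPSG")
})

test_that("rules survive a JSON round-trip", {
  tf <- withr::local_tempfile(fileext = ".json")
  writeRules(defaultRules(), tf)
  back <- readRules(tf)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]@name, defaultRules()[[i]]@name)
    expect_identical(back[[i]]@refPositions, defaultRules()[[i]]@refPositions)
    expect_identical(back[[i]]@bfAllowed, defaultRules()[[i]]@bfAllowed)
    expect_identical(back[[i]]@motif, defaultRules()[[i]]@motif)
  }
})

test_that("criterion evaluation covers BF, nonBF, gap and off-set residues", {
  rules <- defaultRules()
  expect_identical(evaluateCriterion(rules[[1]], "E")$verdict, "BF")
  expect_identical(evaluateCriterion(rules[[1]], "T")$verdict, "nonBF")
  expect_identical(evaluateCriterion(rules[[3]], "Y")$verdict, "nonBF")
  expect_identical(evaluateCriterion(rules[[2]], "-")$verdict,
                   "indeterminate")
  # a residue in neither set is absence of evidence, not a verdict
  expect_identical(evaluateCriterion(rules[[1]], "W")$verdict,
                   "indeterminate")
  # SLBB: exact motif for BF, any gap-free mismatch for nonBF
  expect_identical(
    evaluateCriterion(rules[[4]], strsplit("GGPSG", "")[[1]])$verdict, "BF")
  expect_identical(
    evaluateCriterion(rules[[4]], strsplit("GGPAG", "")[[1]])$verdict,
    "nonBF")
  expect_identical(
    evaluateCriterion(rules[[4]], c("G", "G", "-", "S", "G"))$verdict,
    "indeterminate")
  expect_error(evaluateCriterion(rules[[4]], "G"), "length")
})

test_that("planted BF and non-BF sequences classify to their truth", {
  sc <- makeReferenceScaffold(600, 7)
  bf <- classifySequence(plantSequence(sc, "BF", 0.7, seed = 1), sc)
  nb <- classifySequence(plantSequence(sc, "nonBF", 0.7, seed = 2), sc)
  expect_identical(bf@overall, "BF")
  expect_identical(nb@overall, "nonBF")
  expect_true(all(bf@evidence$verdict == "BF"))
  expect_true(all(nb@evidence$verdict == "nonBF"))
  expect_gt(bf@fesSupport, nb@fesSupport)
})

test_that("a chimeric fingerprint yields an ambiguous verdict", {
  sc <- makeReferenceScaffold(600, 7)
  rec <- plantSequence(sc, "BF", 1, seed = 3)
  chars <- strsplit(as.character(rec)[[1]], "")[[1]]
  chars[367] <- "Y"  # BF NADH site, non-BF FMN site
  chim <- proteinRecord("chimera", paste(chars, collapse = ""))
  res <- classifySequence(chim, sc)
  expect_identical(res@overall, "ambiguous")
  expect_setequal(unique(res@evidence$verdict), c("BF", "nonBF"))
})

test_that("an empty rules list leaves every sequence ambiguous", {
  sc <- makeReferenceScaffold(600, 7)
  set <- classifyBatch(plantSequence(sc, "BF", 1, seed = 4), sc,
                       rules = list())
  expect_identical(unname(classCalls(set)), "ambiguous")
})

test_that("unrelated sequences are refused below the identity floor", {
  sc <- makeReferenceScaffold(600, 7)
  set.seed(5)
  junk <- proteinRecord("junk", randomProtein(80))
  res <- classifySequence(junk, sc)
  expect_identical(res@overall, "ambiguous")
  expect_match(res@note, "refused")
  expect_true(all(res@evidence$verdict == "indeterminate"))
})

test_that("a batch of one equals the single-sequence result", {
  sc <- makeReferenceScaffold(600, 7)
  rec <- plantSequence(sc, "nonBF", 0.8, seed = 6)
  single <- classifySequence(rec, sc)
  batch <- classifyBatch(rec, sc)
  expect_length(batch@results, 1L)
  expect_identical(batch@results[[1]]@overall, single@overall)
  expect_identical(batch@results[[1]]@evidence, single@evidence)
})

test_that("classification is invariant to input order and duplicates", {
  sc <- makeReferenceScaffold(600, 7)
  recs <- c(plantSequence(sc, "BF", 0.75, seed = 7, id = "x"),
            plantSequence(sc, "nonBF", 0.75, seed = 8, id = "y"),
            plantSequence(sc, "BF", 0.75, seed = 9, id = "z"))
  fwd <- classCalls(classifyBatch(recs, sc))
  rev <- classCalls(classifyBatch(rev(recs), sc))
  expect_identical(fwd[names(rev)], rev)
  dup <- classCalls(classifyBatch(c(recs, recs[1]), sc))
  expect_identical(unname(dup[4]), unname(fwd["x"]))
})

test_that("noiseless plants are recovered perfectly", {
  sc <- makeReferenceScaffold(600, 13)
  ds <- generateDataset(10, 10, c(1, 1), seed = 13)
  set <- classifyBatch(ds$records, ds$scaffold)
  expect_identical(unname(classCalls(set)), ds$truth$class)
  expect_identical(unname(classSummary(set)[["ambiguous"]]), 0L)
})
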