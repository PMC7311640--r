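test_that("column trimming keeps gapless blocks and drops gappy columns", {
  block <- c(a = "MKVH", b = "MKVH", c = "MKVH")
  out <- trimColumns(block, 1)
  expect_identical(ncol(out$sequences), 4L)
  expect_identical(out$kept, 1:4)

  gappy <- c(a = "M-VH", b = "MKVH", c = "M-VH", d = "MKVH")
  out <- trimColumns(gappy, 0.6)
  expect_identical(out$kept, c(1L, 3L, 4L))  # column 2 is 50% gaps

  expect_identical(trimColumns(gappy, 0)$kept, 1:4)
  allGap <- c(a = "--", b = "--")
  expect_error(trimColumns(allGap, 0.5), "no columns")
})

test_that("survivor count equals a brute-force column census", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(3:8, 1); L <- sample(10:40, 1)
    mat <- matrix(sample(c(AA20, "-"), n * L, replace = TRUE,
                         prob = c(rep(1, 20), 8)), n, L)
    thr <- runif(1, 0.2, 0.9)
    census <- sum(vapply(seq_len(L), function(j)
      mean(mat[, j] != "-") >= thr, logical(1)))
    if (census == 0) next
    expect_length(trimColumns(mat, thr)$kept, census)
  }
})

test_that("pairwise distances follow the closed forms", {
  expect_equal(pairwiseDistance("MKVH", "MKVH", "p"), 0)
  expect_equal(pairwiseDistance("MKVH", "MKVH", "poisson"), 0)
  expect_equal(pairwiseDistance("MKVH", "MKWW", "p"), 0.5)
  expect_equal(pairwiseDistance("MKVH", "MKWW", "poisson"), -log(0.5))
  expect_error(pairwiseDistance("M-", "-M", "p"), "no shared")
  expect_error(pairwiseDistance("MK", "WW", "poisson"), "p >= 1")
})

test_that("p-distance equals the column-count oracle on random pairs", {
  set.seed(77)
  for (i in 1:20) {
    L <- sample(20:60, 1)
    a <- paste(sample(c(AA20, "-"), L, TRUE, prob = c(rep(1, 20), 4)),
               collapse = "")
    b <- paste(sample(c(AA20, "-"), L, TRUE, prob = c(rep(1, 20), 4)),
               collapse = "")
    shared <- mapply(function(x, y) x != "-" && y != "-",
                     strsplit(a, "")[[1]], strsplit(b, "")[[1]])
    if (!any(shared)) next
    expect_equal(pairwiseDistance(a, b, "p"), pDistOracle(a, b))
  }
})

test_that("neighbor joining recovers a hand-built additive 4-taxon tree", {
  # unrooted tree ((A:1,B:2):1,C:3,D:4) - pendant lengths 1,2,3,4 and an
  # internal edge of 1
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  d <- ape::cophenetic.phylo(tr)
  rec <- njTree(d)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), rec)), 0)
  expect_equal(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
})

test_that("three taxa resolve to the closed-form star", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- njTree(d)
  # closed form: x_a = (d_ab + d_ac - d_bc)/2 etc.
  len <- setNames(tree$edge.length[order(tree$edge[, 2])][1:3],
                  tree$tip.label)
  expect_equal(unname(len[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("NJ is exact on additive matrices and stable to taxon permutation", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    d <- ape::cophenetic.phylo(tr)
    rec <- njTree(d)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
    perm <- sample(n)
    rec2 <- njTree(d[perm, perm])
    expect_equal(as.numeric(ape::dist.topo(rec, rec2)), 0)
  }
})

test_that("NJ tolerates tiny noise on 20 taxa and clamps negative branches", {
  set.seed(66)
  hits <- 0L
  for (i in 1:10) {
    tr <- ape::rtree(20, rooted = FALSE)
    d <- ape::cophenetic.phylo(tr)
    noise <- matrix(stats::rnorm(400, sd = 1e-6), 20)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    rec <- suppressWarnings(njTree(pmax(d + noise, 0)))
    hits <- hits + (ape::dist.topo(tr, rec) == 0)
  }
  expect_identical(hits, 10L)

  dBad <- matrix(c(0, 1, 1, 10, 1, 0, 1, 1, 1, 1, 0, 1, 10, 1, 1, 0), 4,
                 dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(tree <- njTree(dBad), "clamped")
  expect_true(all(tree$edge.length >= 0))
})

test_that("matrix validation rejects malformed distances", {
  d <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(njTree(d), "3 taxa")
  d3 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(njTree(d3), "symmetric")
})

test_that("monophyly is an edge bipartition test", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(isMonophyletic(tr, "A"))          # pendant edge
  expect_true(isMonophyletic(tr, c("A", "B")))
  expect_true(isMonophyletic(tr, c("C", "D")))
  expect_false(isMonophyletic(tr, c("A", "C"))) # straddles the split
  m <- isMonophyletic(tr, c("A", "B"))
  expect_false(is.null(attr(m, "edge")))
  expect_error(isMonophyletic(tr, c("A", "Z")), "unknown")
  expect_error(isMonophyletic(tr, c("A", "B", "C", "D")), "proper subset")
})

test_that("class-diverged synthetic sets give a non-BF clade", {
  succ <- 0L
  for (s in 1:5) {
    ds <- generateDataset(5, 5, c(0.88, 0.95), seed = 2000 + s,
                          classDivergence = 0.3)
    tree <- betaSubunitTree(ds$records, ds$scaffold, model = "poisson")
    nb <- ds$truth$id[ds$truth$class == "nonBF"]
    succ <- succ + isTRUE(isMonophyletic(tree, nb))
  }
  expect_gte(succ, 4L)
})

test_that("trees write as Newick with branch lengths", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(njTree(d), tf)
  txt <- readLines(tf)
  expect_match(txt, "^\\(.*a:.*\\);$")
  back <- ape::read.tree(tf)
  expect_setequal(back$tip.label, c("a", "b", "c"))
})
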