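test_that("projections are distinct-index subsets with the right size and law", {
  # d = n forces every projection to be the full feature set
  full <- sampleProjections(5, m = 3, d = 5, seed = 1)
  expect_true(all(vapply(full, identical, logical(1), y = 1:5)))
  expect_error(sampleProjections(5, m = 2, d = 6, seed = 1), "exceeds")
  expect_identical(sampleProjections(40, 20, 7, seed = 3),
                   sampleProjections(40, 20, 7, seed = 3))
  # empirical inclusion frequency ~ m*d/n within 4 binomial SD
  nFeat <- 150; m <- 800; d <- 12
  pr <- sampleProjections(nFeat, m, d, seed = 5)
  counts <- tabulate(unlist(pr), nFeat)
  expect_true(all(vapply(pr, function(s) length(unique(s)) == d, logical(1))))
  p <- d / nFeat
  se <- sqrt(m * p * (1 - p))
  expect_true(all(abs(counts - m * p) <= 4 * se))
})

test_that("relative importance reproduces the hand-computed aggregation", {
  mkTree <- function(feature, gain, n) {
    structure(list(nodes = list(feature = feature, gain = gain, n = n),
                   classes = c("A", "B")), class = "mcfsTree")
  }
  ensemble <- list(
    list(tree = mkTree(c(1L, 2L, NA, NA, NA), c(0.8, 0.5, 0, 0, 0),
                       c(10, 4, 6, 2, 2)), wAcc = 0.9, nTree = 10),
    list(tree = mkTree(c(2L, NA, NA), c(1.0, 0, 0), c(8, 5, 3)),
         wAcc = 0.5, nTree = 8),
    list(tree = mkTree(c(1L, 3L, NA, NA, NA), c(0.3, 0.2, 0, 0, 0),
                       c(3, 2, 1, 1, 1)), wAcc = 1.0, nTree = 6))
  ri <- relativeImportance(ensemble, nFeatures = 4, u = 1, v = 1)
  # hand evaluation:
  # f1: 0.9 * 0.8 * (10/10) + 1.0 * 0.3 * (3/6)          = 0.87
  # f2: 0.9 * 0.5 * (4/10)  + 0.5 * 1.0 * (8/8)          = 0.68
  # f3: 1.0 * 0.2 * (2/6)                                 = 1/15
  expect_equal(ri, c(0.87, 0.68, 1 / 15, 0), tolerance = 1e-12)
  # doubling the ensemble doubles every score
  expect_equal(relativeImportance(c(ensemble, ensemble), 4), 2 * ri,
               tolerance = 1e-12)
  # exponents act on the stated terms
  ri22 <- relativeImportance(ensemble, 4, u = 2, v = 2)
  expect_equal(ri22[1], 0.81 * 0.8 * 1 + 1 * 0.3 * 0.25, tolerance = 1e-12)
  # node larger than its tree is corrupted
  bad <- list(list(tree = mkTree(c(1L, NA, NA), c(0.5, 0, 0), c(9, 4, 5)),
                   wAcc = 1, nTree = 8))
  expect_error(relativeImportance(bad, 2), "corrupted")
})

test_that("rankFeatures aggregates exactly like relativeImportance over its ensemble", {
  out <- generateTable(syntheticSpec(nPerClass = c(A = 12, B = 12, C = 16),
                                     nFeatures = 15, nInformative = 3,
                                     seed = 6))
  res <- rankFeatures(out$table, mcfsConfig(m = 15, t = 2, d = 6, seed = 2),
                      returnEnsemble = TRUE)
  ri <- relativeImportance(res$ensemble, nFeatures = 15)
  e <- riScores(res$ranking)
  expect_equal(e$ri, sort(ri, decreasing = TRUE), tolerance = 1e-12)
  expect_equal(retainedCount(res$ranking), sum(ri > 0))
  # determinism
  again <- rankFeatures(out$table, mcfsConfig(m = 15, t = 2, d = 6, seed = 2))
  expect_identical(riScores(again), e)
})

test_that("the recovered top set is stable under sample and feature reordering", {
  # the Monte Carlo realization changes with the data layout, but on a
  # strong-signal table the recovered top features must not
  out <- generateTable(syntheticSpec(nPerClass = c(A = 15, B = 15, C = 20),
                                     nFeatures = 12, nInformative = 3,
                                     noiseRate = 0, seed = 3))
  v <- tableValues(out$table)
  y <- as.character(classLabels(out$table))
  planted <- sort(colnames(v)[out$informative])
  cfg <- mcfsConfig(m = 60, t = 2, d = 5, seed = 9)
  top3 <- function(tab) sort(topFeatures(rankFeatures(tab, cfg), 3))
  expect_equal(top3(FeatureTable(v, y)), planted)
  rows <- withSeed(1, sample(nrow(v)))
  cols <- withSeed(2, sample(ncol(v)))
  expect_equal(top3(FeatureTable(v[rows, ], y[rows])), planted)
  expect_equal(top3(FeatureTable(v[, cols], y)), planted)
})

test_that("planted features dominate the ranking on noise-free tables", {
  hits <- 0
  for (seed in 1:10) {
    out <- generateTable(syntheticSpec(nPerClass = c(A = 20, B = 30, C = 40),
                                       nFeatures = 60, nInformative = 6,
                                       noiseRate = 0, seed = seed))
    rk <- riScores(rankFeatures(out$table,
                                mcfsConfig(m = 80, t = 2, seed = seed)))
    planted <- colnames(tableValues(out$table))[out$informative]
    minPlanted <- min(rk$ri[rk$feature %in% planted])
    maxOther <- max(rk$ri[!rk$feature %in% planted])
    if (minPlanted > maxOther) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("permuted labels leave no feature consistently on top across seeds", {
  out <- generateTable(syntheticSpec(nPerClass = c(A = 15, B = 15, C = 20),
                                     nFeatures = 30, nInformative = 3,
                                     seed = 4))
  v <- tableValues(out$table)
  y <- as.character(classLabels(out$table))
  tops <- vapply(1:6, function(seed) {
    perm <- withSeed(seed * 100, sample(length(y)))
    rk <- rankFeatures(FeatureTable(v, y[perm]),
                       mcfsConfig(m = 40, t = 2, seed = seed))
    riScores(rk)$feature[1]
  }, character(1))
  expect_gt(length(unique(tops)), 1)
})

test_that("ranking round-trips through its TSV form", {
  out <- generateTable(syntheticSpec(nPerClass = c(A = 10, B = 14),
                                     nFeatures = 10, nInformative = 2,
                                     seed = 2))
  rk <- rankFeatures(out$table, mcfsConfig(m = 10, t = 2, seed = 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRanking(rk, path)
  back <- readRanking(path)
  expect_equal(riScores(back)$feature, riScores(rk)$feature)
  expect_equal(retainedCount(back), retainedCount(rk))
})
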