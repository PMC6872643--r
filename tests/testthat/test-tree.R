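test_that("entropy matches hand values and rejects empty input", {
  expect_equal(entropyBits(rep("A", 5)), 0)
  expect_equal(entropyBits(c("A", "A", "A", "A", "B", "B", "B", "B")), 1.0)
  expect_equal(entropyBits(c("A", "A", "B", "C")), 1.5)
  expect_error(entropyBits(character(0)), "empty")
})

test_that("information gain matches closed forms and the brute-force oracle", {
  p <- c("A", "A", "A", "A", "B", "B", "B", "B")
  expect_equal(informationGain(p, rep("A", 4), rep("B", 4)), 1.0)
  expect_equal(informationGain(rep("A", 6), rep("A", 2), rep("A", 4)), 0)
  lhs <- c("A", "A", "A", "B")
  rhs <- c("A", "B", "B", "B")
  expect_equal(informationGain(p, lhs, rhs), oracleIG(p, lhs, rhs),
               tolerance = 1e-12)
  expect_error(informationGain(p, lhs, lhs), "partition")
  # random partitions against the oracle
  set.seed(1)
  for (i in 1:50) {
    parent <- sample(c("A", "B", "C"), sample(4:12, 1), replace = TRUE)
    cut <- sample(seq_len(length(parent) - 1), 1)
    l <- parent[seq_len(cut)]
    r <- parent[-seq_len(cut)]
    expect_equal(informationGain(parent, l, r), oracleIG(parent, l, r),
                 tolerance = 1e-12)
    expect_gte(informationGain(parent, l, r), -1e-12)
    expect_lte(informationGain(parent, l, r),
               entropyBits(parent) + 1e-12)
  }
})

test_that("single-class input yields one leaf; a separating feature splits at 0.5", {
  x <- matrix(c(0, 1, 2), ncol = 1)
  t1 <- growTree(x, rep("A", 3))
  expect_true(is.na(t1$nodes$feature[1]))
  x2 <- cbind(noise = c(5, 5, 5, 5), f0 = c(0, 0, 1, 3))
  t2 <- growTree(x2, c("B", "B", "A", "A"), minLeaf = 1)
  expect_equal(t2$nodes$feature[1], 2L)
  expect_equal(t2$nodes$threshold[1], 0.5)
  expect_true(all(is.na(t2$nodes$feature[-1])))
  expect_equal(as.character(predict(t2, x2)), c("B", "B", "A", "A"))
})

test_that("grown trees equal the exhaustive best-split oracle on small tables", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(4:10, 1)
    p <- sample(1:4, 1)
    x <- matrix(sample(0:3, n * p, replace = TRUE), n, p)
    y <- factor(sample(c("A", "B", "C")[seq_len(sample(2:3, 1))], n,
                       replace = TRUE))
    if (nlevels(droplevels(y)) < 1) next
    for (minLeaf in c(1, 2)) {
      grown <- growTree(x, y, minLeaf = minLeaf)
      expect_true(sameTree(nestedTree(grown),
                           oracleTree(x, y, minLeaf = minLeaf)),
                  info = sprintf("case %d minLeaf %d", i, minLeaf))
    }
  }
})

test_that("unpruned trees reach 100% training accuracy on consistent data", {
  set.seed(21)
  for (i in 1:10) {
    n <- 40
    x <- matrix(sample(0:5, n * 5, replace = TRUE), n, 5)
    key <- apply(x, 1, paste, collapse = "/")
    # labels are a function of the feature vector, so no contradictions
    y <- factor(c("A", "B", "C")[(as.integer(factor(key)) %% 3) + 1])
    tr <- growTree(x, y, minLeaf = 1)
    expect_equal(as.character(predict(tr, x)), as.character(y))
  }
})

test_that("weighted accuracy is the mean of per-class recalls", {
  x <- matrix(c(0, 0, 0, 1, 1, 1, 1, 1, 1, 1), ncol = 1)
  y <- rep(c("A", "B"), c(3, 7))
  tr <- growTree(x, y, minLeaf = 1)
  expect_equal(weightedAccuracy(tr, x, y)$wAcc, 1.0)
  # a stump trained on pure B predicts B everywhere: recall A = 0, B = 1
  trB <- growTree(matrix(1, 2, 1), c("B", "B"))
  expect_equal(weightedAccuracy(trB, x, y)$wAcc, 0.5)
  # random 3-class case against an independent recall-mean computation
  set.seed(3)
  x3 <- matrix(sample(0:4, 60, replace = TRUE), 30, 2)
  y3 <- sample(c("A", "B", "C"), 30, replace = TRUE)
  tr3 <- growTree(x3[1:20, ], y3[1:20], minLeaf = 2)
  got <- weightedAccuracy(tr3, x3[21:30, ], y3[21:30])$wAcc
  pred <- as.character(predict(tr3, x3[21:30, ]))
  truth <- y3[21:30]
  want <- mean(vapply(unique(truth),
                      function(cl) mean(pred[truth == cl] == cl), numeric(1)))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(weightedAccuracy(tr3, x3[0, , drop = FALSE], character(0)),
               "empty")
})

test_that("trees serialize to nested JSON with split and leaf records", {
  x <- cbind(f0 = c(0, 0, 1, 3))
  tr <- growTree(x, c("B", "B", "A", "A"), minLeaf = 1)
  obj <- jsonlite::fromJSON(treeToJSON(tr), simplifyVector = TRUE)
  expect_equal(obj$split_feature, "f0")
  expect_equal(obj$split_threshold, 0.5)
  expect_equal(obj$n_samples, 4L)
  expect_equal(obj$info_gain, 1.0)
  expect_equal(obj$left$leaf_class, "B")
  expect_equal(obj$right$leaf_class, "A")
})
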