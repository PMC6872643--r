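test_that("a single threshold condition is found when one feature separates", {
  x <- cbind(f0 = c(1, 2, 1, 3, 0, 0, 0, 0),
             noise = c(1, 0, 1, 0, 1, 0, 1, 0))
  pos <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  rule <- growRule(x, pos, "A")
  expect_equal(rule@conditions$feature, "f0")
  expect_equal(rule@conditions$op, ">=")
  expect_equal(rule@conditions$threshold, 1)
  expect_equal(rule@coverage, c(4, 0))
})

test_that("grown first conditions match the brute-force FOIL oracle", {
  set.seed(17)
  for (i in 1:120) {
    n <- sample(8:30, 1)
    p <- sample(1:5, 1)
    x <- matrix(rpois(n * p, 1.3), n, p,
                dimnames = list(NULL, sprintf("f%d", seq_len(p))))
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    want <- oracleFoilBest(x, pos)
    rule <- growRule(x, pos, "A")
    if (is.null(want)) {
      expect_equal(nrow(rule@conditions), 0)
    } else {
      expect_equal(match(rule@conditions$feature[1], colnames(x)),
                   want$feature)
      expect_equal(rule@conditions$op[1], want$op)
      expect_equal(rule@conditions$threshold[1], want$threshold)
    }
  }
})

test_that("grown rules cover no grow-set negatives on separable data", {
  set.seed(23)
  for (i in 1:20) {
    n <- 30
    x <- matrix(rpois(n * 4, 1), n, 4,
                dimnames = list(NULL, sprintf("f%d", 1:4)))
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    x[pos, 1] <- x[pos, 1] + 2  # force separability on f1
    x[!pos, 1] <- 0
    rule <- growRule(x, pos, "A")
    expect_equal(rule@coverage[2], 0)
  }
})

test_that("inseparable grow sets yield the empty rule for the caller to reject", {
  x <- cbind(f = c(1, 1, 0, 0))
  rule <- growRule(x, c(TRUE, FALSE, TRUE, FALSE), "A")
  expect_equal(nrow(rule@conditions), 0)
})

test_that("pruning drops harmful trailing conditions and never hurts the metric", {
  # last condition loses a positive without removing prune-set negatives
  xp <- cbind(f1 = c(2, 2, 2, 0, 0), f2 = c(1, 1, 0, 1, 0))
  posP <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  rule <- new("Rule",
              conditions = data.frame(feature = c("f1", "f2"),
                                      op = c(">=", ">="),
                                      threshold = c(1, 1),
                                      stringsAsFactors = FALSE),
              consequent = "A", coverage = c(NA_real_, NA_real_))
  pruned <- pruneRule(rule, xp, posP)
  expect_equal(nrow(pruned@conditions), 1)
  expect_equal(pruned@conditions$feature, "f1")
  # an already-optimal rule is unchanged
  ruleOpt <- new("Rule",
                 conditions = data.frame(feature = "f1", op = ">=",
                                         threshold = 1,
                                         stringsAsFactors = FALSE),
                 consequent = "A", coverage = c(NA_real_, NA_real_))
  expect_equal(pruneRule(ruleOpt, xp, posP)@conditions, ruleOpt@conditions)
  # property: pruned metric >= original metric on the prune set
  metricOf <- function(r, x, pos) {
    m <- mcRules:::.conditionsMask(r@conditions, x)
    p <- sum(m & pos); n <- sum(m & !pos)
    if (p + n == 0) 0 else (p - n) / (p + n)
  }
  set.seed(31)
  for (i in 1:40) {
    n <- sample(10:25, 1)
    x <- matrix(rpois(n * 3, 1), n, 3,
                dimnames = list(NULL, c("f1", "f2", "f3")))
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    conds <- data.frame(feature = sample(colnames(x), 3, replace = TRUE),
                        op = sample(c(">=", "<="), 3, replace = TRUE),
                        threshold = sample(0:2, 3, replace = TRUE),
                        stringsAsFactors = FALSE)
    r0 <- new("Rule", conditions = conds, consequent = "A",
              coverage = c(NA_real_, NA_real_))
    pr <- pruneRule(r0, x, pos)
    expect_gte(metricOf(pr, x, pos), metricOf(r0, x, pos) - 1e-12)
    expect_lte(nrow(pr@conditions), nrow(r0@conditions))
  }
})

test_that("rule application follows strict first-match order with a default", {
  rs <- new("RuleSet",
            rules = list(
              new("Rule", conditions = data.frame(feature = "f1", op = ">=",
                                                  threshold = 1,
                                                  stringsAsFactors = FALSE),
                  consequent = "A", coverage = c(NA_real_, NA_real_)),
              new("Rule", conditions = data.frame(feature = "f1", op = ">=",
                                                  threshold = 2,
                                                  stringsAsFactors = FALSE),
                  consequent = "B", coverage = c(NA_real_, NA_real_))),
            defaultClass = "C", classes = c("A", "B", "C"))
  x <- cbind(f1 = c(0, 1, 5))
  expect_equal(as.character(applyRuleSet(rs, x)), c("C", "A", "A"))
  expect_error(applyRuleSet(rs, cbind(g = 1)), "unknown feature 'f1'")
})

test_that("noise-free rule-generated tables are re-learned decision-equivalently", {
  out <- generateTable(syntheticSpec(nPerClass = c(A = 60, B = 60, C = 80),
                                     nFeatures = 30, nInformative = 2,
                                     noiseRate = 0.05, seed = 12))
  rs <- learnRuleSet(out$table, seed = 1)
  pred <- applyRuleSet(rs, out$table)
  want <- applyRuleSet(out$truth, out$table)
  expect_equal(as.character(pred), as.character(want))
  expect_equal(as.character(pred), as.character(classLabels(out$table)))
  expect_equal(defaultClass(rs), "C")  # largest class is the default
})

test_that("rule induction handles classes processed smallest-first", {
  # class order: ascending census, ties by name; biggest becomes default
  v <- rbind(matrix(c(2, 0), 5, 2, byrow = TRUE),
             matrix(c(0, 2), 8, 2, byrow = TRUE),
             matrix(0, 12, 2))
  colnames(v) <- c("fA", "fB")
  y <- rep(c("A", "B", "C"), c(5, 8, 12))
  rs <- learnRuleSet(v, labels = y, seed = 2)
  expect_equal(defaultClass(rs), "C")
  cons <- vapply(ruleList(rs), function(r) r@consequent, character(1))
  expect_equal(unique(cons), c("A", "B"))  # A (smallest) first
})

test_that("optimization passes do not change the first grown-and-pruned rule", {
  out <- generateTable(syntheticSpec(nPerClass = c(A = 40, B = 40, C = 60),
                                     nFeatures = 20, nInformative = 4,
                                     noiseRate = 0.1, seed = 7))
  rs0 <- learnRuleSet(out$table, optimizationPasses = 0, seed = 5)
  rs2 <- learnRuleSet(out$table, optimizationPasses = 2, seed = 5)
  expect_equal(rs0@rules[[1]]@conditions, rs2@rules[[1]]@conditions)
})

test_that("learned rule sets always yield a total prediction function", {
  set.seed(41)
  for (i in 1:5) {
    n <- 60
    x <- matrix(rpois(n * 6, 1), n, 6,
                dimnames = list(NULL, sprintf("f%d", 1:6)))
    y <- sample(c("A", "B", "C"), n, replace = TRUE)  # pure noise labels
    rs <- learnRuleSet(x, labels = y, seed = i)
    pred <- applyRuleSet(rs, x)
    expect_false(anyNA(pred))
    expect_true(all(as.character(pred) %in% c("A", "B", "C")))
  }
})

test_that("rule text round-trips through format and parse", {
  out <- generateTable(syntheticSpec(nPerClass = c(A = 30, B = 30, C = 40),
                                     nFeatures = 15, nInformative = 3,
                                     seed = 3))
  rs <- learnRuleSet(out$table, seed = 1)
  back <- parseRuleText(formatRuleSet(rs))
  expect_equal(defaultClass(back), defaultClass(rs))
  expect_equal(length(ruleList(back)), length(ruleList(rs)))
  for (i in seq_along(rs@rules)) {
    expect_equal(back@rules[[i]]@conditions, rs@rules[[i]]@conditions)
    expect_equal(back@rules[[i]]@consequent, rs@rules[[i]]@consequent)
  }
  x <- tableValues(out$table)
  expect_equal(applyRuleSet(back, x), applyRuleSet(rs, x))
  # JSON round-trip too
  back2 <- rulesFromJSON(rulesJSON(rs))
  expect_equal(applyRuleSet(back2, x), applyRuleSet(rs, x))
  expect_equal(back2@rules[[1]]@coverage, rs@rules[[1]]@coverage)
})

test_that("separable six-feature fixtures reach CV MCC >= 0.95 under 10 folds", {
  out <- generateTable(syntheticSpec(nPerClass = c(A = 60, B = 60, C = 80),
                                     nFeatures = 6, nInformative = 2,
                                     noiseRate = 0, seed = 21))
  x <- tableValues(out$table)
  y <- classLabels(out$table)
  folds <- stratifiedFolds(y, 10, seed = 2)
  pred <- character(length(y))
  for (f in 1:10) {
    rs <- learnRuleSet(x[folds != f, ], labels = y[folds != f], seed = f)
    pred[folds == f] <- as.character(applyRuleSet(rs, x[folds == f, ]))
  }
  expect_gte(multiClassMCC(confusionCounts(as.character(y), pred)), 0.95)
})
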