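test_that("generation is deterministic given the seed and varies across seeds", {
  spec <- syntheticSpec(nPerClass = c(A = 15, B = 20, C = 25),
                        nFeatures = 40, nInformative = 4, seed = 9)
  a <- generateTable(spec)
  b <- generateTable(spec)
  expect_identical(tableValues(a$table), tableValues(b$table))
  expect_identical(as.character(classLabels(a$table)),
                   as.character(classLabels(b$table)))
  spec2 <- syntheticSpec(nPerClass = c(A = 15, B = 20, C = 25),
                         nFeatures = 40, nInformative = 4, seed = 10)
  c_ <- generateTable(spec2)
  expect_false(identical(tableValues(a$table), tableValues(c_$table)))
})

test_that("labels equal the ground-truth rule set's predictions before noise", {
  spec <- syntheticSpec(nPerClass = c(A = 20, B = 20, C = 20),
                        nFeatures = 50, nInformative = 2, noiseRate = 0,
                        seed = 2)
  out <- generateTable(spec)
  expect_equal(as.character(applyRuleSet(out$truth, out$table)),
               as.character(classLabels(out$table)))
  # also with background noise present: rules only touch planted columns
  specN <- syntheticSpec(nPerClass = c(A = 20, B = 20, C = 20),
                         nFeatures = 50, nInformative = 2, noiseRate = 0.1,
                         seed = 2)
  outN <- generateTable(specN)
  expect_equal(as.character(applyRuleSet(outN$truth, outN$table)),
               as.character(classLabels(outN$table)))
})

test_that("label noise flips only labels, and about the requested fraction", {
  base <- syntheticSpec(nPerClass = c(A = 20, B = 20, C = 20),
                        nFeatures = 50, nInformative = 2, noiseRate = 0,
                        labelNoise = 0, seed = 5)
  noisy <- syntheticSpec(nPerClass = c(A = 20, B = 20, C = 20),
                         nFeatures = 50, nInformative = 2, noiseRate = 0,
                         labelNoise = 0.1, seed = 5)
  a <- generateTable(base)
  b <- generateTable(noisy)
  expect_identical(tableValues(a$table), tableValues(b$table))
  flipped <- sum(as.character(classLabels(a$table)) !=
                   as.character(classLabels(b$table)))
  expect_equal(flipped, round(0.1 * 60))
})

test_that("background nonzero frequency sits within 3 binomial SE of noiseRate", {
  rate <- 0.05
  spec <- syntheticSpec(nPerClass = c(A = 40, B = 60), nFeatures = 200,
                        nInformative = 4, noiseRate = rate, seed = 13)
  out <- generateTable(spec)
  v <- tableValues(out$table)[, -out$informative]
  n <- length(v)
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(mean(v > 0) - rate), 3 * se)
})

test_that("inconsistent or malformed generator specs are rejected", {
  # a rule on the default (largest) class is contradictory by construction
  inf <- data.frame(feature = 1, class = "C", threshold = 1, rule = 1)
  expect_error(syntheticSpec(nPerClass = c(A = 5, B = 5, C = 9),
                             nFeatures = 10, informative = inf),
               "default class")
  # the same feature cannot drive rules of two classes
  inf2 <- data.frame(feature = c(2, 2), class = c("A", "B"),
                     threshold = c(1, 1), rule = c(1, 2))
  spec2 <- syntheticSpec(nPerClass = c(A = 5, B = 5, C = 9), nFeatures = 10,
                         informative = inf2)
  expect_error(generateTable(spec2), "distinct")
  # thresholds below 1 would make the default class unreachable
  inf3 <- data.frame(feature = 1, class = "A", threshold = 0, rule = 1)
  expect_error(syntheticSpec(nPerClass = c(A = 5, B = 9), nFeatures = 10,
                             informative = inf3), "threshold")
})

test_that("the study-shaped default spec generates quickly at full size", {
  started <- proc.time()[["elapsed"]]
  out <- generateTable(syntheticSpec(seed = 3))
  elapsed <- proc.time()[["elapsed"]] - started
  expect_equal(nSamples(out$table), 235L + 447L + 796L)
  expect_equal(nFeatures(out$table), 993L)
  expect_equal(length(out$informative), 25L)
  src <- table(featureSources(out$table))
  expect_equal(sort(as.integer(src)), c(149L, 243L, 259L, 342L))
  expect_lt(elapsed, 30)
})

test_that("conjunctive generating rules produce conjunction-consistent labels", {
  inf <- data.frame(feature = c(3, 7, 11), class = c("A", "A", "B"),
                    threshold = c(1, 2, 1), rule = c(1, 1, 2))
  spec <- syntheticSpec(nPerClass = c(A = 12, B = 12, C = 16),
                        nFeatures = 20, informative = inf, noiseRate = 0,
                        seed = 8)
  out <- generateTable(spec)
  v <- tableValues(out$table)
  lab <- as.character(classLabels(out$table))
  expect_true(all(v[lab == "A", 3] >= 1 & v[lab == "A", 7] >= 2))
  expect_true(all(v[lab == "C", c(3, 7, 11)] == 0))
})
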