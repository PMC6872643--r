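# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive everything from first principles (no calls
# into the code paths they verify).

# Shannon entropy straight from the definition.
oracleEntropy <- function(labels) {
  p <- as.vector(table(labels))
  p <- p[p > 0] / length(labels)
  -sum(p * log2(p))
}

oracleIG <- function(parent, left, right) {
  n <- length(parent)
  oracleEntropy(parent) -
    (length(left) * oracleEntropy(left) +
       length(right) * oracleEntropy(right)) / n
}

# Exhaustive best-split search: every (feature, midpoint-threshold) pair,
# ties to lowest feature then lowest threshold, strict 1e-12 improvement.
oracleBestSplit <- function(x, y, minLeaf) {
  best <- NULL
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    for (q in seq_len(length(v) - 1)) {
      thr <- (v[q] + v[q + 1]) / 2
      left <- x[, j] <= thr
      if (sum(left) < minLeaf || sum(!left) < minLeaf) next
      g <- oracleIG(y, y[left], y[!left])
      if (is.null(best) || g > best$gain + 1e-12) {
        best <- list(gain = g, feature = j, threshold = thr)
      }
    }
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

# Exhaustive-search tree with the same stopping rules as the grower; nested
# list representation.
oracleTree <- function(x, y, minLeaf = 2, depth = 0, maxDepth = 0) {
  cnt <- table(y)
  majority <- names(cnt)[which.max(cnt)]  # first max = lowest level index
  pure <- oracleEntropy(y) == 0
  deep <- maxDepth > 0 && depth >= maxDepth
  if (pure || deep || length(y) < 2 * minLeaf) {
    return(list(leaf = majority, n = length(y)))
  }
  best <- oracleBestSplit(x, y, minLeaf)
  if (is.null(best)) return(list(leaf = majority, n = length(y)))
  left <- x[, best$feature] <= best$threshold
  list(feature = best$feature, threshold = best$threshold, gain = best$gain,
       n = length(y),
       left = oracleTree(x[left, , drop = FALSE], y[left], minLeaf,
                         depth + 1, maxDepth),
       right = oracleTree(x[!left, , drop = FALSE], y[!left], minLeaf,
                          depth + 1, maxDepth))
}

# Flatten a grown mcfsTree into the same nested form for comparison.
nestedTree <- function(tree, node = 1L) {
  nd <- tree$nodes
  if (is.na(nd$feature[node])) {
    return(list(leaf = tree$classes[nd$leafClass[node]], n = nd$n[node]))
  }
  list(feature = nd$feature[node], threshold = nd$threshold[node],
       gain = nd$gain[node], n = nd$n[node],
       left = nestedTree(tree, nd$left[node]),
       right = nestedTree(tree, nd$right[node]))
}

sameTree <- function(a, b, tol = 1e-12) {
  if (!is.null(a$leaf) || !is.null(b$leaf)) {
    return(identical(a$leaf, b$leaf) && a$n == b$n)
  }
  a$feature == b$feature && abs(a$threshold - b$threshold) <= tol &&
    abs(a$gain - b$gain) <= tol && a$n == b$n &&
    sameTree(a$left, b$left, tol) && sameTree(a$right, b$right, tol)
}

# Classical binary MCC from the 2x2 table (TP = cm[1,1] for class 1).
oracleBinaryMCC <- function(cm) {
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# Independent per-class metrics by explicit one-vs-rest relabelling.
oraclePerClass <- function(cm, cl) {
  classes <- rownames(cm)
  i <- match(cl, classes)
  b <- matrix(0, 2, 2)
  for (r in seq_along(classes)) {
    for (co in seq_along(classes)) {
      b[if (r == i) 1 else 2, if (co == i) 1 else 2] <-
        b[if (r == i) 1 else 2, if (co == i) 1 else 2] + cm[r, co]
    }
  }
  list(recall = if (sum(b[1, ]) == 0) 0 else b[1, 1] / sum(b[1, ]),
       precision = if (sum(b[, 1]) == 0) 0 else b[1, 1] / sum(b[, 1]),
       mcc = oracleBinaryMCC(b))
}

# Brute-force best first FOIL-gain condition over all (feature, op,
# observed-threshold) candidates; same tie order as the grower.
oracleFoilBest <- function(x, pos) {
  p0 <- sum(pos); n0 <- sum(!pos)
  base <- log2(p0 / (p0 + n0))
  best <- NULL
  for (j in seq_len(ncol(x))) {
    for (op in c(">=", "<=")) {
      for (thr in sort(unique(x[, j]))) {
        cov <- if (op == ">=") x[, j] >= thr else x[, j] <= thr
        p1 <- sum(pos & cov); n1 <- sum(!pos & cov)
        if (p1 == 0) next
        if (p1 + n1 == p0 + n0) next  # no-op condition
        g <- p1 * (log2(p1 / (p1 + n1)) - base)
        if (g <= 1e-12) next
        if (is.null(best) || g > best$gain + 1e-12) {
          best <- list(gain = g, feature = j, op = op, threshold = thr)
        }
      }
    }
  }
  best
}

# Small labelled fixture table builder.
makeTable <- function(values, labels, featureNames = NULL) {
  values <- as.matrix(values)
  if (!is.null(featureNames)) colnames(values) <- featureNames
  FeatureTable(values, labels)
}
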