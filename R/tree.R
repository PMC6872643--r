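#' Shannon entropy of a label multiset
#'
#' @param labels Non-empty vector of class labels.
#' @return Entropy in bits, \eqn{-\sum_c p_c \log_2 p_c}.
#' @export
#' @examples
#' entropyBits(c("A", "A", "B", "B"))  # 1 bit
entropyBits <- function(labels) {
  if (length(labels) == 0) stop("entropy of an empty label set is undefined")
  p <- table(labels)
  p <- p[p > 0] / length(labels)
  -sum(p * log2(p))
}

#' Information gain of a binary partition
#'
#' \eqn{H(parent) - [|L|/|parent| H(L) + |R|/|parent| H(R)]}; always >= 0.
#' \code{left} and \code{right} must partition \code{parent} as multisets.
#'
#' @param parent,left,right Label vectors.
#' @return Information gain in bits.
#' @export
#' @examples
#' informationGain(c("A","A","B","B"), c("A","A"), c("B","B"))  # 1 bit
informationGain <- function(parent, left, right) {
  if (!identical(sort(as.character(parent)),
                 sort(as.character(c(left, right))))) {
    stop("left and right must partition parent as multisets")
  }
  n <- length(parent)
  entropyBits(parent) -
    (length(left) * entropyBits(left) + length(right) * entropyBits(right)) / n
}

#' Grow an information-gain decision tree
#'
#' Greedy binary CART-style induction: at each node the (feature, threshold)
#' pair maximizing information gain is chosen, with thresholds at midpoints
#' between consecutive distinct observed values and the test "value <=
#' threshold" sending samples left. Recursion stops at pure nodes, zero best
#' gain, or the stop limits. Ties are broken toward the lowest feature index,
#' then the lowest threshold, so the result is deterministic.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Class label per sample (factor or character).
#' @param minLeaf Minimum samples per leaf (default 2).
#' @param maxDepth Depth cap; 0 (default) means none.
#' @return An object of class \code{"mcfsTree"}: a list with the flat node
#'   table (\code{feature}, \code{threshold}, \code{n}, \code{gain},
#'   \code{left}, \code{right}, \code{leafClass}) and the class levels.
#' @export
#' @examples
#' x <- matrix(c(0, 0, 1, 2), ncol = 1)
#' growTree(x, c("A", "A", "B", "B"), minLeaf = 1)
growTree <- function(x, y, minLeaf = 2, maxDepth = 0) {
  x <- as.matrix(x)
  if (nrow(x) < 1 || ncol(x) < 1) stop("need >= 1 sample and >= 1 feature")
  y <- if (is.factor(y)) y else factor(y)
  if (length(y) != nrow(x)) stop("one label per row required")
  nodes <- cpp_grow_tree(x, as.integer(y) - 1L, nlevels(y),
                         as.integer(minLeaf), as.integer(maxDepth))
  structure(list(nodes = nodes, classes = levels(y),
                 featureNames = colnames(x), nTrain = nrow(x)),
            class = "mcfsTree")
}

#' Predict classes with a grown tree
#'
#' @param object An \code{"mcfsTree"} from [growTree()].
#' @param newdata Numeric matrix with the same feature columns the tree was
#'   grown on.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.mcfsTree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  nd <- object$nodes
  cls <- cpp_predict_tree(nd$feature, nd$threshold, nd$left, nd$right,
                          nd$leafClass, newdata)
  factor(object$classes[cls], levels = object$classes)
}

#' @export
print.mcfsTree <- function(x, ...) {
  nInternal <- sum(!is.na(x$nodes$feature))
  cat("Information-gain decision tree:", nInternal, "splits,",
      sum(is.na(x$nodes$feature)), "leaves,", x$nTrain, "training samples\n")
  invisible(x)
}

#' Weighted accuracy of a tree on a test set
#'
#' The unweighted mean of per-class recalls over the classes present in the
#' test set, so that rare classes count as much as common ones. A test class
#' the tree never predicts (e.g. unseen in training) contributes recall 0.
#'
#' @param tree An \code{"mcfsTree"}.
#' @param x Test matrix, samples x features (same columns as training).
#' @param y Test labels.
#' @return A list with \code{wAcc} in [0, 1] and \code{nTreeSamples}, the
#'   number of samples the tree was grown on.
#' @export
weightedAccuracy <- function(tree, x, y) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty test set")
  y <- as.character(y)
  pred <- as.character(predict(tree, x))
  recalls <- vapply(unique(y), function(cl) mean(pred[y == cl] == cl),
                    numeric(1))
  list(wAcc = mean(recalls), nTreeSamples = tree$nTrain)
}

#' Serialize a tree to nested JSON
#'
#' @param tree An \code{"mcfsTree"}.
#' @return A JSON string of nested node records (\code{split_feature},
#'   \code{split_threshold}, \code{n_samples}, \code{info_gain},
#'   \code{left}/\code{right} or \code{leaf_class}).
#' @export
treeToJSON <- function(tree) {
  nd <- tree$nodes
  rec <- function(i) {
    if (is.na(nd$feature[i])) {
      list(leaf_class = tree$classes[nd$leafClass[i]], n_samples = nd$n[i])
    } else {
      fname <- if (!is.null(tree$featureNames)) {
        tree$featureNames[nd$feature[i]]
      } else {
        nd$feature[i]
      }
      list(split_feature = fname, split_threshold = nd$threshold[i],
           n_samples = nd$n[i], info_gain = nd$gain[i],
           left = rec(nd$left[i]), right = rec(nd$right[i]))
    }
  }
  jsonlite::toJSON(rec(1L), auto_unbox = TRUE, digits = NA)
}
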