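#' Confusion matrix from label vectors
#'
#' @param truth,predicted Equal-length label vectors over a shared class set.
#' @param classes Optional class ordering; default the sorted union of the
#'   levels observed in either vector.
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @export
#' @examples
#' confusionCounts(c("A", "A", "B"), c("A", "B", "B"))
confusionCounts <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  if (is.null(classes)) {
    classes <- sort(unique(c(as.character(truth), as.character(predicted))))
  }
  t1 <- factor(as.character(truth), levels = classes)
  p1 <- factor(as.character(predicted), levels = classes)
  if (anyNA(t1) || anyNA(p1)) stop("labels outside the given class set")
  m <- table(t1, p1)
  matrix(as.integer(m), nrow = length(classes),
         dimnames = list(classes, classes))
}

#' Per-class accuracy, precision, recall and one-vs-rest MCC
#'
#' For class c: recall (= the class's individual accuracy) is
#' \code{cm[c,c] / rowsum}, precision \code{cm[c,c] / colsum}, and MCC the
#' binary Matthews correlation of the one-vs-rest collapse of the matrix.
#' Ratios of 0/0 (empty row, empty predicted column, degenerate MCC
#' denominator) are 0 by convention, so reports stay defined on degenerate
#' folds.
#'
#' @param cm Confusion matrix as from [confusionCounts()].
#' @return data.frame with columns \code{class}, \code{accuracy},
#'   \code{precision}, \code{recall}, \code{mcc}.
#' @export
perClassMetrics <- function(cm) {
  if (length(cm) == 0) stop("empty confusion matrix")
  N <- sum(cm)
  classes <- rownames(cm)
  res <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- N - tp - fn - fp
    recall <- .safeDiv(tp, tp + fn)
    precision <- .safeDiv(tp, tp + fp)
    denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
    data.frame(class = classes[i], accuracy = recall, precision = precision,
               recall = recall, mcc = mcc, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

.safeDiv <- function(a, b) if (b == 0) 0 else a / b

#' Multi-class Matthews correlation coefficient (RK statistic)
#'
#' Gorodkin's K-category correlation:
#' \deqn{R_K = \frac{N \cdot tr(C) - \sum_k r_k c_k}
#'   {\sqrt{(N^2 - \sum_k r_k^2)(N^2 - \sum_k c_k^2)}}}
#' with \eqn{r_k, c_k} the row and column sums of the confusion matrix
#' \eqn{C} and \eqn{N} the total; 1 for perfect prediction, about 0 at
#' chance. A zero denominator (e.g. all samples predicted into one class)
#' yields 0 by convention. For K = 2 it equals the classical binary MCC.
#'
#' @param cm Confusion matrix as from [confusionCounts()].
#' @return A number in [-1, 1].
#' @export
#' @examples
#' multiClassMCC(diag(c(5, 3, 2)))  # 1
multiClassMCC <- function(cm) {
  if (length(cm) == 0 || sum(cm) == 0) stop("empty confusion matrix")
  N <- sum(cm)
  r <- rowSums(cm)
  c_ <- colSums(cm)
  num <- N * sum(diag(cm)) - sum(r * c_)
  den <- sqrt(N^2 - sum(r^2)) * sqrt(N^2 - sum(c_^2))
  if (den == 0) 0 else num / den
}

#' Full performance report from labels or a confusion matrix
#'
#' @param truth,predicted Label vectors (ignored when \code{cm} is given).
#' @param classes Optional class ordering.
#' @param cm Optionally, a ready confusion matrix.
#' @return A [PerformanceReport-class].
#' @export
performanceReport <- function(truth = NULL, predicted = NULL, classes = NULL,
                              cm = NULL) {
  if (is.null(cm)) cm <- confusionCounts(truth, predicted, classes)
  new("PerformanceReport", confusion = cm, perClass = perClassMetrics(cm),
      overallAccuracy = sum(diag(cm)) / sum(cm),
      multiClassMCC = multiClassMCC(cm))
}

#' Accessors for PerformanceReport
#'
#' @param x A [PerformanceReport-class].
#' @name PerformanceReport-accessors
#' @aliases confusion perClass overallAccuracy
#' @return \code{confusion}: the K x K matrix; \code{perClass}: the
#'   per-class metric data.frame; \code{overallAccuracy}: trace over total.
NULL

#' @rdname PerformanceReport-accessors
#' @export
setMethod("confusion", "PerformanceReport", function(x) x@confusion)

#' @rdname PerformanceReport-accessors
#' @export
setMethod("perClass", "PerformanceReport", function(x) x@perClass)

#' @rdname PerformanceReport-accessors
#' @export
setMethod("overallAccuracy", "PerformanceReport", function(x) x@overallAccuracy)

#' @describeIn multiClassMCC Method on a [PerformanceReport-class].
#' @param report A [PerformanceReport-class].
#' @export
reportMCC <- function(report) report@multiClassMCC

setMethod("show", "PerformanceReport", function(object) {
  cat(sprintf("PerformanceReport: %d samples, overall accuracy %.4f, ",
              sum(object@confusion), object@overallAccuracy))
  cat(sprintf("multi-class MCC %.4f\n", object@multiClassMCC))
  print(object@perClass, row.names = FALSE, digits = 4)
})

#' Serialize a PerformanceReport to JSON
#'
#' @param report A [PerformanceReport-class].
#' @return A JSON string with the confusion matrix, per-class metrics,
#'   overall accuracy and multi-class MCC.
#' @export
reportJSON <- function(report) {
  jsonlite::toJSON(list(
    classes = rownames(report@confusion),
    confusion = unname(report@confusion),
    per_class = report@perClass,
    overall_accuracy = report@overallAccuracy,
    multi_class_mcc = report@multiClassMCC), auto_unbox = TRUE, digits = NA)
}

#' Write a confusion matrix as TSV
#'
#' @param cm Confusion matrix (or a [PerformanceReport-class]).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeConfusion <- function(cm, path) {
  if (is(cm, "PerformanceReport")) cm <- cm@confusion
  df <- data.frame(true_class = rownames(cm), cm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
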