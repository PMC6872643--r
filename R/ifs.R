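# Cross-validated rule-learner performance on a fixed feature subset.
# Folds are supplied so every subset is scored on identical partitions.
.cvReport <- function(x, y, folds, ripperParams, seedBase) {
  classes <- levels(y)
  pred <- character(length(y))
  for (f in sort(unique(folds))) {
    test <- folds == f
    rs <- do.call(learnRuleSet, c(
      list(table = x[!test, , drop = FALSE], labels = y[!test],
           seed = deriveSeed(seedBase, paste0("fold", f))),
      ripperParams))
    pred[test] <- as.character(applyRuleSet(rs, x[test, , drop = FALSE]))
  }
  performanceReport(as.character(y), pred, classes = classes)
}

.flattenReport <- function(k, report) {
  pc <- perClass(report)
  row <- data.frame(k = k, overallAccuracy = report@overallAccuracy,
                    multiClassMCC = report@multiClassMCC)
  for (i in seq_len(nrow(pc))) {
    row[[paste0("accuracy.", pc$class[i])]] <- pc$accuracy[i]
    row[[paste0("precision.", pc$class[i])]] <- pc$precision[i]
    row[[paste0("mcc.", pc$class[i])]] <- pc$mcc[i]
  }
  row
}

#' Incremental feature selection over a ranking
#'
#' Scans nested top-k feature subsets (k = 1, 2, ..., kMax with step 1) along
#' the ranked list. For each k the rule learner is trained and evaluated by
#' stratified cross-validation on the top-k feature columns; the folds are a
#' pure function of (labels, seed) and shared across all k, so the per-k
#' scores differ only through the features. The optimum subset maximizes the
#' multi-class MCC, ties resolved to the smallest k.
#'
#' @param table A [FeatureTable-class].
#' @param ranked A [RankedFeatureList-class] from [rankFeatures()].
#' @param kMax Largest subset size; default the ranking's RI > 0 retained
#'   count.
#' @param cvFolds Number of folds (default 10); every class must have at
#'   least this many samples.
#' @param seed Integer seed (default 1).
#' @param ripperParams Named list of [learnRuleSet()] options (\code{folds},
#'   \code{minCovered}, \code{optimizationPasses}, \code{prune}).
#' @return An [IFSResult-class].
#' @export
runIFS <- function(table, ranked, kMax = NULL, cvFolds = 10, seed = 1,
                   ripperParams = list()) {
  if (is.null(kMax)) kMax <- max(1L, retainedCount(ranked))
  if (kMax > nrow(riScores(ranked))) {
    stop("kMax exceeds the number of ranked features")
  }
  x <- tableValues(table)
  y <- droplevels(classLabels(table))
  folds <- stratifiedFolds(y, cvFolds, seed)
  ordered <- topFeatures(ranked, kMax)
  reports <- vector("list", kMax)
  rows <- vector("list", kMax)
  for (k in seq_len(kMax)) {
    xk <- x[, ordered[seq_len(k)], drop = FALSE]
    rep_ <- .cvReport(xk, y, folds, ripperParams,
                      deriveSeed(seed, paste0("ifs_k", k)))
    reports[[k]] <- rep_
    rows[[k]] <- .flattenReport(k, rep_)
  }
  records <- do.call(rbind, rows)
  opt <- selectOptimum(records)
  new("IFSResult", records = records, reports = reports,
      optimumK = opt$optimumK,
      optimumFeatures = ordered[seq_len(opt$optimumK)])
}

#' Pick the optimum subset size from IFS records
#'
#' Argmax of the multi-class MCC over the per-k records; ties resolve to the
#' smallest k (parsimony).
#'
#' @param records data.frame with columns \code{k} and \code{multiClassMCC}
#'   (an [IFSResult-class] works too).
#' @return List with \code{optimumK} and \code{optimumMCC}.
#' @export
#' @examples
#' selectOptimum(data.frame(k = 1:3, multiClassMCC = c(0.5, 0.9, 0.9)))
selectOptimum <- function(records) {
  if (is(records, "IFSResult")) records <- records@records
  if (nrow(records) == 0) stop("no IFS records")
  best <- which(records$multiClassMCC >=
                  max(records$multiClassMCC) - 1e-12)
  pick <- best[which.min(records$k[best])]
  list(optimumK = as.integer(records$k[pick]),
       optimumMCC = records$multiClassMCC[pick])
}

#' Accessors for IFSResult
#'
#' @param x An [IFSResult-class].
#' @name IFSResult-accessors
#' @aliases ifsRecords optimumK optimumFeatures
#' @return \code{ifsRecords}: the per-k record data.frame; \code{optimumK}:
#'   the selected subset size; \code{optimumFeatures}: its feature names.
NULL

#' @rdname IFSResult-accessors
#' @export
setMethod("ifsRecords", "IFSResult", function(x) x@records)

#' @rdname IFSResult-accessors
#' @export
setMethod("optimumK", "IFSResult", function(x) x@optimumK)

#' @rdname IFSResult-accessors
#' @export
setMethod("optimumFeatures", "IFSResult", function(x) x@optimumFeatures)

setMethod("show", "IFSResult", function(object) {
  r <- object@records
  cat(sprintf(
    "IFSResult: k = 1..%d; optimum k = %d (MCC %.4f, accuracy %.4f)\n",
    max(r$k), object@optimumK,
    r$multiClassMCC[r$k == object@optimumK],
    r$overallAccuracy[r$k == object@optimumK]))
})

#' Write IFS records as TSV (one row per k)
#'
#' @param x An [IFSResult-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeIFS <- function(x, path) {
  utils::write.table(ifsRecords(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
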