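#' Random-subset significance test for a top-k feature set
#'
#' Compares the cross-validated multi-class MCC of the ranked top-k subset
#' against a null distribution built from \code{nRandom} same-size subsets
#' drawn uniformly without replacement from the feature pool (all features by
#' default, or only the RI > 0 retained ones). Every subset — top-k and
#' random alike — is scored with the rule learner under the same stratified
#' folds. The add-one empirical p-value
#' \code{(1 + #\{null >= top\}) / (nRandom + 1)} is never exactly 0.
#'
#' @param table A [FeatureTable-class].
#' @param ranked A [RankedFeatureList-class].
#' @param k Subset size (default 25).
#' @param nRandom Number of random subsets (default 1000).
#' @param cvFolds Cross-validation folds (default 10).
#' @param seed Integer seed (default 1).
#' @param pool \code{"all"} (default) or \code{"retained"}: where random
#'   subsets are drawn from.
#' @param ripperParams Named list of [learnRuleSet()] options.
#' @return A [RandomSubsetTestResult-class].
#' @export
randomSubsetTest <- function(table, ranked, k = 25, nRandom = 1000,
                             cvFolds = 10, seed = 1,
                             pool = c("all", "retained"),
                             ripperParams = list()) {
  pool <- match.arg(pool)
  if (nRandom < 1) stop("nRandom must be >= 1")
  x <- tableValues(table)
  y <- droplevels(classLabels(table))
  poolNames <- if (pool == "all") colnames(x) else
    topFeatures(ranked, max(1L, retainedCount(ranked)))
  if (k > length(poolNames)) {
    stop("k exceeds the number of features in the sampling pool")
  }
  folds <- stratifiedFolds(y, cvFolds, seed)
  top <- topFeatures(ranked, k)
  topMCC <- .cvReport(x[, top, drop = FALSE], y, folds, ripperParams,
                      deriveSeed(seed, "topk"))@multiClassMCC
  subsets <- withSeed(deriveSeed(seed, "null_subsets"), {
    lapply(seq_len(nRandom), function(i) sample(poolNames, k))
  })
  nullMCCs <- vapply(seq_len(nRandom), function(i) {
    .cvReport(x[, subsets[[i]], drop = FALSE], y, folds, ripperParams,
              deriveSeed(seed, paste0("null", i)))@multiClassMCC
  }, numeric(1))
  new("RandomSubsetTestResult", topKMCC = topMCC, nullMCCs = nullMCCs,
      k = as.integer(k), nRandom = as.integer(nRandom),
      empiricalP = (1 + sum(nullMCCs >= topMCC)) / (nRandom + 1))
}

setMethod("show", "RandomSubsetTestResult", function(object) {
  cat(sprintf(
    "RandomSubsetTestResult: top-%d MCC %.4f vs %d random subsets\n",
    object@k, object@topKMCC, object@nRandom))
  cat(sprintf("  null MCC range [%.4f, %.4f], empirical p = %.4g\n",
              min(object@nullMCCs), max(object@nullMCCs), object@empiricalP))
})

#' Serialize a random-subset test result to JSON
#'
#' @param x A [RandomSubsetTestResult-class].
#' @return A JSON string.
#' @export
validationJSON <- function(x) {
  jsonlite::toJSON(list(
    k = x@k, n_random = x@nRandom, top_k_mcc = x@topKMCC,
    empirical_p = x@empiricalP, null_mccs = x@nullMCCs),
    auto_unbox = TRUE, digits = NA)
}
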