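#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<- rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' FeatureTable: annotation-count profiles with class labels
#'
#' An S4 container for a samples-by-features table of nonnegative
#' functional-annotation counts with one categorical label per sample
#' (e.g. the bacterial phylum of each strain). Extends
#' \linkS4class{SummarizedExperiment}: the single \code{"counts"} assay is
#' stored features-by-samples, labels live in \code{colData()$label}, and the
#' source database of each feature (ARDB/CARD/KEGG/VFDB, when recognizable
#' from a name prefix) in \code{rowData()$source}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @seealso [FeatureTable()], [readFeatureTable()], [filterMinClassSize()]
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  v <- assay(object, "counts")
  if (is.null(rownames(v))) return("feature names are required")
  if (anyDuplicated(rownames(v))) {
    dup <- rownames(v)[duplicated(rownames(v))][1]
    return(sprintf("duplicate feature name: '%s'", dup))
  }
  if (anyNA(v)) return("counts contain missing values")
  if (any(v < 0)) return("counts must be >= 0")
  if (!"label" %in% colnames(colData(object))) return("colData must carry 'label'")
  lab <- colData(object)$label
  if (!is.factor(lab)) return("labels must be a factor")
  if (anyNA(lab)) return("every sample needs a label")
  TRUE
})

#' RankedFeatureList: features ordered by relative importance
#'
#' Result of Monte Carlo feature selection: each feature with its RI score,
#' sorted non-increasingly (ties broken by original column order), plus the
#' number of features with strictly positive RI.
#'
#' @slot entries data.frame with columns \code{feature}, \code{ri},
#'   \code{rank}.
#' @slot retainedCount Integer, number of features with RI > 0.
#' @seealso [rankFeatures()]
#' @export
setClass("RankedFeatureList",
  representation(entries = "data.frame", retainedCount = "integer"))

setValidity("RankedFeatureList", function(object) {
  e <- object@entries
  if (!all(c("feature", "ri", "rank") %in% names(e))) {
    return("entries needs columns feature, ri, rank")
  }
  if (any(e$ri < 0)) return("RI scores must be >= 0")
  if (is.unsorted(rev(e$ri))) return("entries must be sorted by non-increasing RI")
  if (object@retainedCount != sum(e$ri > 0)) {
    return("retainedCount must equal the number of features with RI > 0")
  }
  TRUE
})

#' Rule: a conjunction of threshold conditions with a class consequent
#'
#' @slot conditions data.frame with columns \code{feature} (name), \code{op}
#'   (\code{">="} or \code{"<="}) and \code{threshold}. An empty data.frame is
#'   the always-firing rule.
#' @slot consequent Predicted class when all conditions hold.
#' @slot coverage Numeric length-2 vector: positives and negatives covered on
#'   the rule's training data (NA when unknown).
#' @seealso [RuleSet], [growRule()]
#' @export
setClass("Rule",
  representation(conditions = "data.frame", consequent = "character",
                 coverage = "numeric"),
  prototype(coverage = c(NA_real_, NA_real_)))

setValidity("Rule", function(object) {
  cd <- object@conditions
  if (nrow(cd) > 0) {
    if (!all(c("feature", "op", "threshold") %in% names(cd))) {
      return("conditions needs columns feature, op, threshold")
    }
    if (!all(cd$op %in% c(">=", "<="))) return("ops must be '>=' or '<='")
  }
  if (length(object@consequent) != 1L) return("consequent must be one class")
  TRUE
})

#' RuleSet: an ordered rule list with a default class
#'
#' Prediction follows first-match semantics: the consequent of the first rule
#' whose conditions all hold, otherwise \code{defaultClass} (the "others"
#' row of a printed rule table).
#'
#' @slot rules List of [Rule] objects, in firing order.
#' @slot defaultClass Class predicted when no rule fires.
#' @slot classes All class names the rule set can emit.
#' @seealso [learnRuleSet()], [applyRuleSet()], [parseRuleText()]
#' @export
setClass("RuleSet",
  representation(rules = "list", defaultClass = "character",
                 classes = "character"))

setValidity("RuleSet", function(object) {
  if (!all(vapply(object@rules, is, logical(1), class2 = "Rule"))) {
    return("rules must be Rule objects")
  }
  if (length(object@defaultClass) != 1L) return("one default class required")
  if (!object@defaultClass %in% object@classes) {
    return("defaultClass must be among classes")
  }
  TRUE
})

#' PerformanceReport: confusion matrix and derived statistics
#'
#' @slot confusion K-by-K integer matrix, rows = true class, columns =
#'   predicted class.
#' @slot perClass data.frame with per-class \code{accuracy} (= recall),
#'   \code{precision}, \code{recall} and one-vs-rest \code{mcc}.
#' @slot overallAccuracy Trace over total.
#' @slot multiClassMCC The K-category Matthews correlation coefficient
#'   (Gorodkin's RK statistic), in [-1, 1].
#' @seealso [performanceReport()], [multiClassMCC()]
#' @export
setClass("PerformanceReport",
  representation(confusion = "matrix", perClass = "data.frame",
                 overallAccuracy = "numeric", multiClassMCC = "numeric"))

#' IFSResult: incremental feature selection scan
#'
#' One record per subset size k (a contiguous 1..kMax range), each holding the
#' cross-validated performance of the rule learner on the top-k features, and
#' the optimum subset (highest multi-class MCC, ties to the smallest k).
#'
#' @slot records data.frame with columns \code{k}, \code{overallAccuracy},
#'   \code{multiClassMCC} and per-class accuracy/precision/MCC columns.
#' @slot reports List of [PerformanceReport] objects, one per k.
#' @slot optimumK Selected subset size.
#' @slot optimumFeatures Names of the top-\code{optimumK} features.
#' @seealso [runIFS()], [selectOptimum()]
#' @export
setClass("IFSResult",
  representation(records = "data.frame", reports = "list",
                 optimumK = "integer", optimumFeatures = "character"))

#' RandomSubsetTestResult: empirical significance of a top-k subset
#'
#' @slot topKMCC Cross-validated multi-class MCC of the ranked top-k subset.
#' @slot nullMCCs MCCs of the randomly drawn same-size subsets.
#' @slot k Subset size.
#' @slot nRandom Number of random subsets.
#' @slot empiricalP Add-one empirical p-value,
#'   \code{(1 + #\{null >= top\}) / (nRandom + 1)}.
#' @seealso [randomSubsetTest()]
#' @export
setClass("RandomSubsetTestResult",
  representation(topKMCC = "numeric", nullMCCs = "numeric", k = "integer",
                 nRandom = "integer", empiricalP = "numeric"))

#' SyntheticSpec: parameters of the synthetic table generator
#'
#' @slot nPerClass Named integer vector: samples per class.
#' @slot nFeatures Total number of features.
#' @slot informative data.frame with columns \code{feature} (column index),
#'   \code{class}, \code{threshold} and \code{rule} (rule id grouping rows
#'   into conjunctions); each rule reads "all its features >= their
#'   thresholds implies its class".
#' @slot defaultClass Class generated when no rule fires.
#' @slot noiseRate Probability that a background cell is nonzero.
#' @slot countProb Geometric parameter of nonzero counts
#'   (count = 1 + Geom(countProb)).
#' @slot labelNoise Fraction of samples whose label is re-randomized.
#' @slot seed Integer seed.
#' @seealso [syntheticSpec()], [generateTable()]
#' @export
setClass("SyntheticSpec",
  representation(nPerClass = "integer", nFeatures = "integer",
                 informative = "data.frame", defaultClass = "character",
                 noiseRate = "numeric", countProb = "numeric",
                 labelNoise = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (length(object@nPerClass) < 2L) return("need >= 2 classes")
  if (is.null(names(object@nPerClass))) return("nPerClass must be named")
  inf <- object@informative
  if (nrow(inf) > 0) {
    if (!all(c("feature", "class", "threshold", "rule") %in% names(inf))) {
      return("informative needs columns feature, class, threshold, rule")
    }
    if (any(inf$feature < 1 | inf$feature > object@nFeatures)) {
      return("informative feature indices must lie in 1..nFeatures")
    }
    if (any(inf$threshold < 1)) return("informative thresholds must be >= 1")
    if (!all(inf$class %in% names(object@nPerClass))) {
      return("informative classes must be generated classes")
    }
    if (object@defaultClass %in% inf$class) {
      return("the default class cannot carry generating rules")
    }
  }
  if (object@noiseRate < 0 || object@noiseRate > 1) return("noiseRate in [0,1]")
  if (object@labelNoise < 0 || object@labelNoise > 1) return("labelNoise in [0,1]")
  if (object@countProb <= 0 || object@countProb > 1) return("countProb in (0,1]")
  if (!object@defaultClass %in% names(object@nPerClass)) {
    return("defaultClass must be a generated class")
  }
  TRUE
})

#' MCFSConfig: Monte Carlo feature selection parameters
#'
#' @slot m Number of random feature subsets ("projections").
#' @slot t Train/test splits per projection, so t*m trees in total.
#' @slot d Features per projection; \code{NA} means the default
#'   \code{max(ceiling(sqrt(p)), ceiling(0.05 * p))}.
#' @slot trainFraction Fraction of samples in each training split.
#' @slot u Exponent on the tree's weighted accuracy in the RI score.
#' @slot v Exponent on the node sample-fraction term.
#' @slot replace Resample training sets with replacement instead of the
#'   default stratified subsampling without replacement.
#' @slot seed Integer seed.
#' @seealso [mcfsConfig()], [rankFeatures()]
#' @export
setClass("MCFSConfig",
  representation(m = "integer", t = "integer", d = "integer",
                 trainFraction = "numeric", u = "numeric", v = "numeric",
                 replace = "logical", seed = "integer"))

setValidity("MCFSConfig", function(object) {
  if (object@m < 1L || object@t < 1L) return("m and t must be >= 1")
  if (!is.na(object@d) && object@d < 1L) return("d must be >= 1")
  if (object@trainFraction <= 0 || object@trainFraction >= 1) {
    return("trainFraction must lie in (0, 1)")
  }
  TRUE
})
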