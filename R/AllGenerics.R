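#' @rdname FeatureTable-accessors
#' @export
setGeneric("tableValues", function(x) standardGeneric("tableValues"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("classCensus", function(x) standardGeneric("classCensus"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("featureSources", function(x) standardGeneric("featureSources"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname RankedFeatureList-accessors
#' @export
setGeneric("riScores", function(x) standardGeneric("riScores"))

#' @rdname RankedFeatureList-accessors
#' @export
setGeneric("retainedCount", function(x) standardGeneric("retainedCount"))

#' @rdname RankedFeatureList-accessors
#' @export
setGeneric("topFeatures", function(x, k) standardGeneric("topFeatures"))

#' @rdname RuleSet-accessors
#' @export
setGeneric("ruleList", function(x) standardGeneric("ruleList"))

#' @rdname RuleSet-accessors
#' @export
setGeneric("defaultClass", function(x) standardGeneric("defaultClass"))

#' @rdname IFSResult-accessors
#' @export
setGeneric("ifsRecords", function(x) standardGeneric("ifsRecords"))

#' @rdname IFSResult-accessors
#' @export
setGeneric("optimumK", function(x) standardGeneric("optimumK"))

#' @rdname IFSResult-accessors
#' @export
setGeneric("optimumFeatures", function(x) standardGeneric("optimumFeatures"))

#' @rdname PerformanceReport-accessors
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))

#' @rdname PerformanceReport-accessors
#' @export
setGeneric("perClass", function(x) standardGeneric("perClass"))

#' @rdname PerformanceReport-accessors
#' @export
setGeneric("overallAccuracy", function(x) standardGeneric("overallAccuracy"))
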