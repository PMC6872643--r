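#' Specify a synthetic annotation-count table
#'
#' Describes a generator for tables with the structure the workflow assumes:
#' several classes of unequal size, sparse nonnegative integer features, a
#' small set of class-informative features whose signal has threshold form,
#' and many uninformative background features. Ground truth is an ordered
#' rule list in the same condition algebra the rule learner emits, so
#' recovery experiments compare like with like.
#'
#' The default is study-shaped: three phyla with censuses 235/447/796, 993
#' features named with ARDB/CARD/KEGG/VFDB-proportioned prefixes, and 25
#' planted single-condition "subtype indicator" rules (split between the two
#' smaller classes, largest class as default). Each non-default sample
#' satisfies exactly one of its class's rules, so all planted features are
#' jointly needed for perfect classification.
#'
#' @param nPerClass Named integer vector of samples per class.
#' @param nFeatures Total features (default 993).
#' @param informative Optional data.frame with columns \code{feature}
#'   (column index), \code{class}, \code{threshold} (>= 1) and \code{rule}
#'   (id grouping rows into one conjunctive rule). \code{NULL} builds the
#'   default planted layout from \code{nInformative}.
#' @param nInformative Number of planted single-condition rules when
#'   \code{informative} is \code{NULL} (default 25).
#' @param defaultClass Class generated when no rule fires; default the
#'   largest class.
#' @param noiseRate Probability a background cell is nonzero (default 0.05).
#' @param countProb Geometric parameter: nonzero counts are
#'   \code{1 + rgeom(countProb)} (default 0.5).
#' @param labelNoise Fraction of samples whose label is re-randomized to a
#'   different class (default 0).
#' @param seed Integer seed (default 1).
#' @return A [SyntheticSpec-class].
#' @export
#' @examples
#' syntheticSpec(nPerClass = c(A = 20, B = 20, C = 20), nFeatures = 50,
#'               nInformative = 2, noiseRate = 0)
syntheticSpec <- function(nPerClass = c(Actinobacteria = 235,
                                        Bacteroidetes = 447,
                                        Firmicutes = 796),
                          nFeatures = 993, informative = NULL,
                          nInformative = 25, defaultClass = NULL,
                          noiseRate = 0.05, countProb = 0.5, labelNoise = 0,
                          seed = 1) {
  nPerClass <- stats::setNames(as.integer(nPerClass), names(nPerClass))
  if (is.null(defaultClass)) {
    defaultClass <- names(nPerClass)[which.max(nPerClass)]
  }
  if (is.null(informative)) {
    informative <- .defaultInformative(nFeatures, nInformative,
                                       setdiff(names(nPerClass), defaultClass))
  }
  new("SyntheticSpec", nPerClass = nPerClass,
      nFeatures = as.integer(nFeatures),
      informative = informative, defaultClass = defaultClass,
      noiseRate = noiseRate, countProb = countProb, labelNoise = labelNoise,
      seed = as.integer(seed))
}

# Planted layout: nInformative single-condition rules assigned round-robin to
# the non-default classes, features scattered across the columns, thresholds
# mostly 1 with every fifth rule at 2 (the count-threshold form a printed
# rule table uses).
.defaultInformative <- function(nFeatures, nInformative, ruleClasses) {
  if (nInformative < 1) {
    return(data.frame(feature = integer(0), class = character(0),
                      threshold = numeric(0), rule = integer(0)))
  }
  if (nInformative > nFeatures) {
    stop("nInformative exceeds nFeatures")
  }
  step <- max(1L, nFeatures %/% (nInformative + 1L))
  feats <- step * seq_len(nInformative)
  if (anyDuplicated(feats) || any(feats > nFeatures)) {
    feats <- seq_len(nInformative)
  }
  data.frame(feature = feats,
             class = rep_len(ruleClasses, nInformative),
             threshold = ifelse(seq_len(nInformative) %% 5L == 0L, 2, 1),
             rule = seq_len(nInformative),
             stringsAsFactors = FALSE)
}

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", sum(object@nPerClass), "samples x", object@nFeatures,
      "features\n")
  cat("classes:", paste(sprintf("%s (%d)", names(object@nPerClass),
                                object@nPerClass), collapse = ", "), "\n")
  cat(sprintf(
    "planted rules: %d (default class %s); noiseRate %g, labelNoise %g, seed %d\n",
    length(unique(object@informative$rule)), object@defaultClass,
    object@noiseRate, object@labelNoise, object@seed))
})

# ARDB/CARD/KEGG/VFDB-proportioned feature names for tables wide enough to
# carry them; plain F_* names otherwise.
.syntheticFeatureNames <- function(p) {
  if (p < 20) return(sprintf("F_%03d", seq_len(p)))
  prop <- c(ARDB = 342, CARD = 259, KEGG = 243, VFDB = 149) / 993
  counts <- diff(c(0, round(cumsum(prop) * p)))
  counts[length(counts)] <- p - sum(counts[-length(counts)])
  unlist(lapply(seq_along(counts), function(i) {
    sprintf("%s: feature_%04d", names(prop)[i], seq_len(counts[i]))
  }), use.names = FALSE)
}

#' Generate a synthetic FeatureTable with known ground truth
#'
#' Deterministic given the spec's seed. Background features are i.i.d.
#' sparse counts across samples and classes. Each non-default-class sample is
#' assigned one of its class's generating rules uniformly at random and its
#' rule features are set to counts meeting the rule thresholds; all other
#' informative features stay 0, so before label noise every label is exactly
#' the ground-truth rule set's prediction. Label noise, applied last, leaves
#' the values matrix untouched.
#'
#' @param spec A [SyntheticSpec-class].
#' @return A list with \code{table} (a [FeatureTable-class]), \code{truth}
#'   (the generating [RuleSet-class]) and \code{informative} (sorted indices
#'   of the planted features).
#' @export
#' @examples
#' out <- generateTable(syntheticSpec(nPerClass = c(A = 10, B = 10, C = 15),
#'                                    nFeatures = 30, nInformative = 4,
#'                                    noiseRate = 0, seed = 3))
#' all(applyRuleSet(out$truth, out$table) == classLabels(out$table))
generateTable <- function(spec) {
  validObject(spec)
  n <- sum(spec@nPerClass)
  p <- spec@nFeatures
  inf <- spec@informative
  if (nrow(inf) > length(unique(inf$feature))) {
    stop("spec error: informative features must be distinct across rules")
  }
  classes <- names(spec@nPerClass)
  featNames <- .syntheticFeatureNames(p)
  truth <- .truthRuleSet(inf, featNames, spec@defaultClass, classes)

  labels0 <- rep(classes, times = spec@nPerClass)
  values <- withSeed(spec@seed, {
    v <- matrix(0, n, p)
    background <- setdiff(seq_len(p), inf$feature)
    if (length(background) > 0 && spec@noiseRate > 0) {
      nz <- matrix(stats::rbinom(n * length(background), 1L,
                                 spec@noiseRate) == 1L,
                   n, length(background))
      v[, background][nz] <- 1 + stats::rgeom(sum(nz), spec@countProb)
    }
    for (cl in setdiff(classes, spec@defaultClass)) {
      ruleIds <- unique(inf$rule[inf$class == cl])
      if (length(ruleIds) == 0) {
        stop("spec error: class '", cl, "' has no generating rule; make it ",
             "the default class or give it a rule")
      }
      rows <- which(labels0 == cl)
      # balanced shuffled partition: each class is an even mixture of its
      # subtypes, so every planted feature carries comparable signal
      pick <- sample(rep_len(ruleIds, length(rows)))
      for (rid in ruleIds) {
        sub <- rows[pick == rid]
        if (length(sub) == 0) next
        conds <- inf[inf$rule == rid, , drop = FALSE]
        for (q in seq_len(nrow(conds))) {
          v[sub, conds$feature[q]] <- conds$threshold[q] +
            stats::rgeom(length(sub), spec@countProb)
        }
      }
    }
    v
  })
  dimnames(values) <- list(sprintf("strain_%04d", seq_len(n)), featNames)

  # generated labels must agree with the generating rule set before noise
  ftCheck <- FeatureTable(values, labels0)
  predicted <- as.character(applyRuleSet(truth, ftCheck))
  if (!all(predicted == labels0)) {
    stop("spec error: inconsistent informative rules (generated pattern of ",
         "sample ", which(predicted != labels0)[1],
         " implies class '", predicted[predicted != labels0][1], "')")
  }

  labels <- labels0
  if (spec@labelNoise > 0) {
    labels <- withSeed(spec@seed + 1L, {
      nFlip <- round(spec@labelNoise * n)
      flip <- sample.int(n, nFlip)
      for (i in flip) {
        labels[i] <- sample(setdiff(classes, labels[i]), 1L)
      }
      labels
    })
  }
  tab <- FeatureTable(values, factor(labels, levels = classes))
  list(table = tab, truth = truth, informative = sort(unique(inf$feature)))
}

.truthRuleSet <- function(inf, featNames, defaultClass, classes) {
  ruleIds <- unique(inf$rule)
  sig <- character(0)
  rules <- lapply(ruleIds, function(rid) {
    conds <- inf[inf$rule == rid, , drop = FALSE]
    key <- paste(sort(paste0(conds$feature, ">=", conds$threshold)),
                 collapse = "&")
    prev <- sig[key]
    if (!is.na(prev) && prev != conds$class[1]) {
      stop("spec error: inconsistent informative rules (identical conditions ",
           "imply classes '", prev, "' and '", conds$class[1], "')")
    }
    sig[key] <<- conds$class[1]
    new("Rule",
        conditions = data.frame(feature = featNames[conds$feature],
                                op = ">=", threshold = conds$threshold,
                                stringsAsFactors = FALSE),
        consequent = conds$class[1], coverage = c(NA_real_, NA_real_))
  })
  new("RuleSet", rules = rules, defaultClass = defaultClass,
      classes = classes)
}
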