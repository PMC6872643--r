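#' Monte Carlo feature selection configuration
#'
#' @param m Number of random feature projections (default 2000).
#' @param t Train/test splits per projection (default 5), giving t*m trees.
#' @param d Features per projection; \code{NA} (default) resolves to
#'   \code{max(ceiling(sqrt(p)), ceiling(0.05 * p))} for p features.
#' @param trainFraction Fraction of samples (per class) in each training
#'   split (default 0.66).
#' @param u,v Exponents on the tree weighted accuracy and the node
#'   sample-fraction term of the RI score (default 1, as in the study design
#'   this package follows).
#' @param replace Draw training samples with replacement instead of the
#'   default stratified subsampling without replacement.
#' @param seed Integer seed (default 1).
#' @return An [MCFSConfig-class] object.
#' @export
#' @examples
#' mcfsConfig(m = 100, t = 3)
mcfsConfig <- function(m = 2000, t = 5, d = NA, trainFraction = 0.66,
                       u = 1, v = 1, replace = FALSE, seed = 1) {
  new("MCFSConfig", m = as.integer(m), t = as.integer(t), d = as.integer(d),
      trainFraction = trainFraction, u = u, v = v, replace = replace,
      seed = as.integer(seed))
}

setMethod("show", "MCFSConfig", function(object) {
  d <- if (is.na(object@d)) "auto" else object@d
  cat(sprintf(
    "MCFSConfig: m = %d projections x t = %d splits (%d trees), d = %s,\n",
    object@m, object@t, object@m * object@t, d))
  cat(sprintf("  trainFraction = %g, u = %g, v = %g, %s, seed = %d\n",
              object@trainFraction, object@u, object@v,
              if (object@replace) "with replacement" else "without replacement",
              object@seed))
})

.resolveD <- function(d, p) {
  if (!is.na(d)) return(as.integer(d))
  as.integer(max(ceiling(sqrt(p)), ceiling(0.05 * p)))
}

#' Draw random feature projections
#'
#' Each of the \code{m} projections is a set of exactly \code{d} distinct
#' feature indices drawn uniformly without replacement.
#'
#' @param nFeatures Total number of features.
#' @param m Number of projections.
#' @param d Projection size.
#' @param seed Integer seed.
#' @return A list of \code{m} sorted integer vectors.
#' @export
#' @examples
#' sampleProjections(10, m = 3, d = 4, seed = 1)
sampleProjections <- function(nFeatures, m, d, seed) {
  if (d > nFeatures) stop("projection size d exceeds the number of features")
  withSeed(seed, {
    lapply(seq_len(m), function(i) sort(sample.int(nFeatures, d)))
  })
}

#' Relative importance scores from a tree ensemble
#'
#' Aggregates, for each feature g, the score
#' \deqn{RI_g = \sum_\tau (wAcc_\tau)^u \sum_{n_g(\tau)} IG(n_g(\tau))
#'   \left(\frac{no.\ in\ n_g(\tau)}{no.\ in\ \tau}\right)^v}
#' over every node split on g in every tree of the ensemble, where
#' \eqn{IG} is the node's information gain, the inner fraction the share of
#' the tree's training samples reaching the node, and \eqn{wAcc} the tree's
#' weighted accuracy on its test split.
#'
#' @param ensemble List of entries, each a list with \code{tree} (an
#'   \code{"mcfsTree"} whose node features index the full feature space),
#'   \code{wAcc} and \code{nTree} (training samples in the tree).
#' @param nFeatures Total number of features scores are reported for.
#' @param u,v Exponents (default 1).
#' @return Numeric vector of RI scores, one per feature; features never split
#'   on score 0.
#' @export
relativeImportance <- function(ensemble, nFeatures, u = 1, v = 1) {
  ri <- numeric(nFeatures)
  for (entry in ensemble) {
    nd <- entry$tree$nodes
    internal <- !is.na(nd$feature)
    if (!any(internal)) next
    feats <- nd$feature[internal]
    if (any(nd$n[internal] > entry$nTree)) {
      stop("corrupted ensemble: node sample count exceeds tree sample count")
    }
    contrib <- nd$gain[internal] * (nd$n[internal] / entry$nTree)^v
    agg <- rowsum(contrib, feats)
    idx <- as.integer(rownames(agg))
    ri[idx] <- ri[idx] + entry$wAcc^u * agg[, 1]
  }
  ri
}

#' Rank features by Monte Carlo relative importance
#'
#' For each of the \code{m} projections, \code{t} stratified train/test
#' splits are drawn; one information-gain tree is grown per (projection,
#' split) on the training samples restricted to the projection's features and
#' evaluated by weighted accuracy on the held-out samples. RI scores are
#' aggregated over all t*m trees and the features sorted by decreasing RI
#' (ties broken by column order). Features with RI > 0 are counted as
#' retained; the rest carry no split information and are discarded by the
#' downstream selection.
#'
#' @param table A [FeatureTable-class] with >= 2 classes.
#' @param config An [MCFSConfig-class]; see [mcfsConfig()].
#' @param minLeaf,maxDepth Tree stop limits (defaults 2 and none).
#' @param returnEnsemble Also return the grown ensemble (memory-heavy; meant
#'   for small inputs).
#' @return A [RankedFeatureList-class]; with \code{returnEnsemble = TRUE}, a
#'   list with elements \code{ranking} and \code{ensemble}.
#' @export
#' @examples
#' tab <- generateTable(syntheticSpec(nPerClass = c(A = 15, B = 15, C = 20),
#'                                    nFeatures = 12, nInformative = 2,
#'                                    seed = 7))$table
#' rankFeatures(tab, mcfsConfig(m = 30, t = 2, seed = 1))
rankFeatures <- function(table, config = mcfsConfig(), minLeaf = 2,
                         maxDepth = 0, returnEnsemble = FALSE) {
  y <- classLabels(table)
  if (nlevels(y) < 2L) stop("need >= 2 classes to rank features")
  if (any(table(y) < 2L)) {
    stop("stratification error: every class needs >= 2 samples")
  }
  x <- tableValues(table)
  p <- ncol(x)
  d <- .resolveD(config@d, p)
  ensemble <- if (returnEnsemble) vector("list", config@m * config@t) else NULL
  ri <- numeric(p)
  withSeed(config@seed, {
    projections <- lapply(seq_len(config@m),
                          function(i) sort(sample.int(p, d)))
    e <- 0L
    for (proj in projections) {
      xp <- x[, proj, drop = FALSE]
      for (s in seq_len(config@t)) {
        train <- if (config@replace) {
          idx <- unlist(lapply(levels(y), function(cl) {
            cidx <- which(y == cl)
            nTrain <- max(1L, min(length(cidx) - 1L,
                                  round(config@trainFraction * length(cidx))))
            sample(cidx, nTrain, replace = TRUE)
          }))
          sort(idx)
        } else {
          .stratifiedSplit(y, config@trainFraction)
        }
        test <- setdiff(seq_len(nrow(x)), unique(train))
        tree <- growTree(xp[train, , drop = FALSE], y[train],
                         minLeaf = minLeaf, maxDepth = maxDepth)
        ev <- weightedAccuracy(tree, xp[test, , drop = FALSE], y[test])
        nd <- tree$nodes
        internal <- !is.na(nd$feature)
        # remap projected column indices back to the full feature space
        nd$feature[internal] <- proj[nd$feature[internal]]
        tree$nodes <- nd
        tree$featureNames <- colnames(x)
        if (any(internal)) {
          contrib <- nd$gain[internal] *
            (nd$n[internal] / ev$nTreeSamples)^config@v
          agg <- rowsum(contrib, nd$feature[internal])
          idx <- as.integer(rownames(agg))
          ri[idx] <- ri[idx] + ev$wAcc^config@u * agg[, 1]
        }
        if (returnEnsemble) {
          e <- e + 1L
          ensemble[[e]] <- list(tree = tree, wAcc = ev$wAcc,
                                nTree = ev$nTreeSamples)
        }
      }
    }
  })
  ord <- order(-ri, seq_len(p))
  entries <- data.frame(feature = colnames(x)[ord], ri = ri[ord],
                        rank = seq_len(p), stringsAsFactors = FALSE)
  ranking <- new("RankedFeatureList", entries = entries,
                 retainedCount = sum(ri > 0))
  if (returnEnsemble) list(ranking = ranking, ensemble = ensemble) else ranking
}

#' Accessors for RankedFeatureList
#'
#' \code{riScores} returns the entries data.frame (feature, ri, rank);
#' \code{retainedCount} the number of features with RI > 0;
#' \code{topFeatures} the names of the k best-ranked features.
#'
#' @param x A [RankedFeatureList-class].
#' @param k Number of top features.
#' @name RankedFeatureList-accessors
#' @aliases riScores retainedCount topFeatures
#' @return See the description.
NULL

#' @rdname RankedFeatureList-accessors
#' @export
setMethod("riScores", "RankedFeatureList", function(x) x@entries)

#' @rdname RankedFeatureList-accessors
#' @export
setMethod("retainedCount", "RankedFeatureList", function(x) x@retainedCount)

#' @rdname RankedFeatureList-accessors
#' @export
setMethod("topFeatures", "RankedFeatureList", function(x, k) {
  if (k > nrow(x@entries)) stop("k exceeds the number of ranked features")
  x@entries$feature[seq_len(k)]
})

setMethod("show", "RankedFeatureList", function(object) {
  cat("RankedFeatureList:", nrow(object@entries), "features,",
      object@retainedCount, "with RI > 0\n")
  print(utils::head(object@entries, 5))
  if (nrow(object@entries) > 5) cat("...\n")
})

#' Write a ranking as TSV (feature, RI score, rank)
#'
#' @param x A [RankedFeatureList-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeRanking <- function(x, path) {
  utils::write.table(riScores(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a ranking written by [writeRanking()]
#'
#' @param path Path to the TSV.
#' @return A [RankedFeatureList-class].
#' @export
readRanking <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  new("RankedFeatureList",
      entries = df[, c("feature", "ri", "rank")],
      retainedCount = sum(df$ri > 0))
}
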