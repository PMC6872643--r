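#' @useDynLib mcRules, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Logical mask of rows satisfying every condition of a conjunction.
.conditionsMask <- function(conds, x) {
  ok <- rep(TRUE, nrow(x))
  if (nrow(conds) == 0) return(ok)
  missing <- setdiff(conds$feature, colnames(x))
  if (length(missing) > 0) {
    stop("schema error: unknown feature '", missing[1], "' in rule")
  }
  for (q in seq_len(nrow(conds))) {
    col <- x[, conds$feature[q]]
    ok <- ok & if (conds$op[q] == ">=") col >= conds$threshold[q] else
      col <= conds$threshold[q]
  }
  ok
}

.rulesCover <- function(rules, x) {
  covered <- rep(FALSE, nrow(x))
  for (r in rules) covered <- covered | .conditionsMask(r@conditions, x)
  covered
}

#' Apply an ordered rule set
#'
#' First-match semantics: each sample is assigned the consequent of the first
#' rule (in listed order) whose conditions all hold, and the default class if
#' none fires.
#'
#' @param rs A [RuleSet-class].
#' @param table A [FeatureTable-class] or numeric matrix with feature column
#'   names covering every feature the rules mention.
#' @return Factor of predicted classes (levels = the rule set's classes).
#' @export
applyRuleSet <- function(rs, table) {
  x <- if (is(table, "FeatureTable")) tableValues(table) else as.matrix(table)
  pred <- rep(rs@defaultClass, nrow(x))
  assigned <- rep(FALSE, nrow(x))
  for (r in rs@rules) {
    fires <- .conditionsMask(r@conditions, x) & !assigned
    pred[fires] <- r@consequent
    assigned <- assigned | fires
  }
  factor(pred, levels = rs@classes)
}

#' Grow one rule by greedy FOIL information gain
#'
#' Starting from the empty conjunction (or from \code{init}'s coverage when
#' revising an existing rule), repeatedly adds the condition
#' \code{feature >= t} or \code{feature <= t} (t an observed value of the
#' feature among currently covered samples) maximizing FOIL information gain
#' \eqn{p_1 (\log_2 \frac{p_1}{p_1+n_1} - \log_2 \frac{p_0}{p_0+n_0})},
#' until the rule covers no negatives or no condition improves. Ties go to
#' the lowest feature index, \code{>=} before \code{<=}, then the lowest
#' threshold.
#'
#' @param x Numeric matrix (grow set), samples x features, with column names.
#' @param positive Logical vector marking the target-class samples.
#' @param consequent Class name the rule predicts.
#' @param init Optional logical vector of initially covered samples.
#' @return A [Rule-class] with training coverage (positives, negatives).
#' @export
growRule <- function(x, positive, consequent, init = NULL) {
  x <- as.matrix(x)
  if (!any(positive)) stop("grow set has no positive samples")
  if (is.null(init)) init <- rep(TRUE, nrow(x))
  g <- cpp_grow_rule(x, as.logical(positive), as.logical(init))
  conds <- data.frame(feature = colnames(x)[g$feature], op = g$op,
                      threshold = g$threshold, stringsAsFactors = FALSE)
  new("Rule", conditions = conds, consequent = consequent,
      coverage = c(g$p, g$n))
}

#' Reduced-error pruning of a rule
#'
#' Final-sequence pruning: among the prefixes of the rule's condition list
#' (never below one condition), keeps the shortest prefix maximizing the
#' pruning metric \eqn{(p - n) / (p + n)} on the pruning set, where p and n
#' are the positives and negatives the prefix covers. The metric never
#' decreases relative to the unpruned rule.
#'
#' @param rule A [Rule-class] grown on a disjoint grow set.
#' @param x Pruning-set matrix.
#' @param positive Logical vector marking target-class pruning samples.
#' @return The pruned [Rule-class], coverage updated to the pruning set.
#' @export
pruneRule <- function(rule, x, positive) {
  x <- as.matrix(x)
  conds <- rule@conditions
  k <- nrow(conds)
  if (k == 0) return(rule)
  mask <- rep(TRUE, nrow(x))
  metric <- numeric(k)
  pAll <- numeric(k)
  nAll <- numeric(k)
  for (L in seq_len(k)) {
    col <- x[, conds$feature[L]]
    mask <- mask & if (conds$op[L] == ">=") col >= conds$threshold[L] else
      col <= conds$threshold[L]
    p <- sum(mask & positive)
    n <- sum(mask & !positive)
    metric[L] <- if (p + n == 0) 0 else (p - n) / (p + n)
    pAll[L] <- p
    nAll[L] <- n
  }
  best <- which.max(metric)  # first max = shortest prefix among equals
  rule@conditions <- conds[seq_len(best), , drop = FALSE]
  rule@coverage <- c(pAll[best], nAll[best])
  rule
}

# ---- description length ---------------------------------------------------

# Total number of candidate conditions in a table (distinct values per
# feature, two operators each); the alphabet size for rule theory bits.
.candidateCount <- function(x) {
  2L * sum(vapply(seq_len(ncol(x)),
                  function(j) length(unique(x[, j])), integer(1)))
}

# Theory bits for one rule with k conditions out of nCand possibilities,
# with the customary 0.5 redundancy factor.
.ruleDL <- function(k, nCand) 0.5 * (log2(k + 1) + k * log2(nCand + 1))

# Description length of a rule list for one target class on data (x, pos):
# theory bits plus binomial-coded exceptions (false positives among covered
# rows, false negatives among uncovered rows).
.rulesetDL <- function(rules, x, pos, nCand) {
  covered <- .rulesCover(rules, x)
  fp <- sum(covered & !pos)
  fn <- sum(!covered & pos)
  ncov <- sum(covered)
  nuncov <- length(covered) - ncov
  theory <- if (length(rules) == 0) 0 else
    sum(vapply(rules, function(r) .ruleDL(nrow(r@conditions), nCand),
               numeric(1)))
  theory + log2(length(covered) + 1) +
    .log2choose(ncov, fp) + .log2choose(nuncov, fn)
}

# Stratified grow/prune split: (folds-1)/folds of positives and of negatives
# go to the grow set. Falls back to growing on everything when the data are
# too small to hold out a pruning set with the positives still represented.
.growPruneSplit <- function(n, pos, folds) {
  grow <- logical(n)
  for (isPos in c(TRUE, FALSE)) {
    idx <- which(pos == isPos)
    if (length(idx) == 0) next
    nGrow <- ceiling(length(idx) * (folds - 1) / folds)
    grow[sample(idx, nGrow)] <- TRUE
  }
  if (!any(pos & grow) || all(grow)) {
    grow <- rep(TRUE, n)
  }
  grow
}

# ---- the learner ----------------------------------------------------------

# Sequential covering for one target class. Returns the accepted rules.
# x/pos are the class-level snapshot; `rules` may carry rules already
# accepted (mop-up after optimization resumes from them).
.coverLoop <- function(rules, x, pos, cl, folds, minCovered, prune, nCand,
                       dlMin = NULL) {
  active <- if (length(rules) == 0) rep(TRUE, nrow(x)) else
    !.rulesCover(rules, x)
  if (is.null(dlMin)) dlMin <- .rulesetDL(rules, x, pos, nCand)
  repeat {
    if (!any(pos & active)) break
    idx <- which(active)
    usePrune <- prune && sum(pos[idx]) >= 2 && length(idx) >= 3
    grow <- if (usePrune) .growPruneSplit(length(idx), pos[idx], folds) else
      rep(TRUE, length(idx))
    growIdx <- idx[grow]
    pruneIdx <- idx[!grow]
    rule <- growRule(x[growIdx, , drop = FALSE], pos[growIdx], cl)
    if (nrow(rule@conditions) == 0) break
    if (usePrune && length(pruneIdx) > 0) {
      rule <- pruneRule(rule, x[pruneIdx, , drop = FALSE], pos[pruneIdx])
      pn <- rule@coverage
      if (sum(pn) > 0 && pn[2] > pn[1]) break  # error rate > 50% held out
    }
    mask <- .conditionsMask(rule@conditions, x)
    pA <- sum(mask & pos & active)
    nA <- sum(mask & !pos & active)
    if (pA < minCovered) break
    rule@coverage <- c(pA, nA)
    dl <- .rulesetDL(c(rules, list(rule)), x, pos, nCand)
    if (dl > dlMin + 64) break
    if (dl < dlMin) dlMin <- dl
    rules[[length(rules) + 1]] <- rule
    active <- active & !mask
  }
  list(rules = rules, dlMin = dlMin)
}

.learnClassRules <- function(x, pos, cl, folds, minCovered,
                             optimizationPasses, prune) {
  nCand <- .candidateCount(x)
  out <- .coverLoop(list(), x, pos, cl, folds, minCovered, prune, nCand)
  rules <- out$rules
  for (pass in seq_len(optimizationPasses)) {
    if (length(rules) == 0) break
    for (i in seq_along(rules)) {
      others <- rules[-i]
      free <- if (length(others) == 0) rep(TRUE, nrow(x)) else
        !.rulesCover(others, x)
      idx <- which(free)
      if (sum(pos[idx]) < minCovered || length(idx) < 3) next
      grow <- .growPruneSplit(length(idx), pos[idx], folds)
      growIdx <- idx[grow]
      pruneIdx <- idx[!grow]
      xg <- x[growIdx, , drop = FALSE]
      variants <- list(rules[[i]])
      if (any(pos[growIdx])) {
        repl <- growRule(xg, pos[growIdx], cl)
        if (nrow(repl@conditions) > 0) {
          if (length(pruneIdx) > 0) {
            repl <- pruneRule(repl, x[pruneIdx, , drop = FALSE],
                              pos[pruneIdx])
          }
          variants[[length(variants) + 1]] <- repl
        }
        init <- .conditionsMask(rules[[i]]@conditions, xg)
        if (any(init & pos[growIdx])) {
          grown <- growRule(xg, pos[growIdx], cl, init = init)
          rev <- rules[[i]]
          rev@conditions <- rbind(rules[[i]]@conditions, grown@conditions)
          if (length(pruneIdx) > 0 && nrow(rev@conditions) > 0) {
            rev <- pruneRule(rev, x[pruneIdx, , drop = FALSE], pos[pruneIdx])
          }
          if (nrow(rev@conditions) > 0) {
            variants[[length(variants) + 1]] <- rev
          }
        }
      }
      if (length(variants) > 1) {
        dls <- vapply(variants, function(v) {
          trial <- rules
          trial[[i]] <- v
          .rulesetDL(trial, x, pos, nCand)
        }, numeric(1))
        rules[[i]] <- variants[[which.min(dls)]]  # ties keep the original
      }
    }
    # rules that no longer pull their weight are dropped, then uncovered
    # positives are mopped up with fresh rules
    keep <- vapply(seq_along(rules), function(i) {
      mask <- .conditionsMask(rules[[i]]@conditions, x)
      prev <- if (i == 1) rep(FALSE, nrow(x)) else
        .rulesCover(rules[seq_len(i - 1)], x)
      sum(mask & pos & !prev) >= minCovered
    }, logical(1))
    rules <- rules[keep]
    out <- .coverLoop(rules, x, pos, cl, folds, minCovered, prune, nCand)
    rules <- out$rules
  }
  # final per-rule coverage, sequentially on the class snapshot
  prev <- rep(FALSE, nrow(x))
  for (i in seq_along(rules)) {
    mask <- .conditionsMask(rules[[i]]@conditions, x) & !prev
    rules[[i]]@coverage <- c(sum(mask & pos), sum(mask & !pos))
    prev <- prev | mask
  }
  rules
}

#' Learn an ordered rule list (RIPPER family)
#'
#' Sequential covering in the RIPPER/JRip tradition. Classes are processed in
#' increasing frequency order (ties by name) and the most frequent class
#' becomes the default ("others") class. For each class: the data are split
#' stratified into grow and prune parts, a rule is grown by FOIL gain
#' ([growRule()]), pruned by reduced error ([pruneRule()]), accepted unless
#' it covers fewer than \code{minCovered} positives, errs on more than half
#' of its held-out coverage, or pushes the class's description length more
#' than 64 bits above the best seen; covered samples are then removed and the
#' loop repeats. Optimization passes revisit each rule with replacement and
#' revision variants chosen by total description length. Samples covered by a
#' class's accepted rules are removed before the next class is processed.
#' Deterministic given \code{seed}.
#'
#' @param table A [FeatureTable-class], or a numeric matrix with
#'   \code{labels}.
#' @param labels Class labels when \code{table} is a matrix.
#' @param folds Grow/prune split granularity: \code{(folds-1)/folds} of the
#'   data grow the rule, the rest prune it (default 3, i.e. 2:1).
#' @param minCovered Minimum positives a rule must newly cover (default 2).
#' @param optimizationPasses Number of optimization sweeps (default 2).
#' @param prune Reduced-error pruning on/off (default on).
#' @param seed Integer seed (default 1).
#' @return A [RuleSet-class].
#' @export
#' @examples
#' x <- matrix(c(1, 1, 0, 0, 0, 0, 2, 3), ncol = 2,
#'             dimnames = list(NULL, c("fA", "fB")))
#' rs <- learnRuleSet(x, labels = c("A", "A", "B", "B"), seed = 1)
#' applyRuleSet(rs, x)
learnRuleSet <- function(table, labels = NULL, folds = 3, minCovered = 2,
                         optimizationPasses = 2, prune = TRUE, seed = 1) {
  if (is(table, "FeatureTable")) {
    x <- tableValues(table)
    y <- classLabels(table)
  } else {
    x <- as.matrix(table)
    y <- labels
  }
  if (is.null(colnames(x))) colnames(x) <- sprintf("F_%04d", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("degenerate dataset: need >= 2 classes")
  census <- base::table(y)
  classOrder <- names(census)[order(as.integer(census), names(census))]
  defaultCl <- classOrder[length(classOrder)]
  remaining <- seq_len(nrow(x))
  rules <- list()
  withSeed(seed, {
    for (cl in classOrder[-length(classOrder)]) {
      xr <- x[remaining, , drop = FALSE]
      clRules <- .learnClassRules(xr, as.character(y[remaining]) == cl, cl,
                                  folds, minCovered, optimizationPasses,
                                  prune)
      rules <- c(rules, clRules)
      if (length(clRules) > 0) {
        covered <- .rulesCover(clRules, xr)
        remaining <- remaining[!covered]
      }
      if (length(remaining) == 0) break
    }
  })
  new("RuleSet", rules = rules, defaultClass = defaultCl,
      classes = levels(y))
}

#' Accessors for RuleSet
#'
#' @param x A [RuleSet-class].
#' @name RuleSet-accessors
#' @aliases ruleList defaultClass
#' @return \code{ruleList}: the ordered list of [Rule-class] objects;
#'   \code{defaultClass}: the class predicted when no rule fires.
NULL

#' @rdname RuleSet-accessors
#' @export
setMethod("ruleList", "RuleSet", function(x) x@rules)

#' @rdname RuleSet-accessors
#' @export
setMethod("defaultClass", "RuleSet", function(x) x@defaultClass)

setMethod("show", "Rule", function(object) {
  cat(.formatRule(object), "\n")
})

setMethod("show", "RuleSet", function(object) {
  cat("RuleSet:", length(object@rules), "rules + default class",
      object@defaultClass, "\n")
  for (line in formatRuleSet(object)) cat(" ", line, "\n")
})
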