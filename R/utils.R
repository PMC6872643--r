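#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{code} with the random number generator seeded at \code{seed},
#' restoring the caller's RNG state afterwards so that package functions are
#' pure with respect to the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @export
#' @examples
#' withSeed(1, runif(1)) == withSeed(1, runif(1))
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' Deterministic derivation used by the pipeline so that one global seed
#' reproducibly drives every stage. The stage name is hashed with a small
#' polynomial rolling hash and folded into the global seed modulo a prime
#' below 2^31.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name, e.g. \code{"rank"}.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
#' @examples
#' deriveSeed(1, "rank")
deriveSeed <- function(seed, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  m <- 2147483587  # prime < 2^31
  h <- 0
  for (u in utf8ToInt(stage)) h <- (h * 131 + u) %% m
  as.integer((abs(as.numeric(seed)) %% m * 7919 + h) %% m + 1)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of \code{k} cross-validation folds, stratifying
#' by class so every fold has a near-proportional class composition. The
#' assignment is a pure function of \code{labels} and \code{seed}.
#'
#' @param labels Factor or character vector of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in \code{1:k}, one per sample.
#' @export
#' @examples
#' stratifiedFolds(rep(c("A", "B"), c(20, 30)), 10, seed = 1)
stratifiedFolds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  if (any(table(labels) < k)) {
    stop("stratification error: every class needs at least ", k, " samples")
  }
  folds <- integer(length(labels))
  withSeed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

# Stratified train/test split: train_fraction per class, without replacement.
# Guarantees at least one train and one test sample per class.
.stratifiedSplit <- function(labels, trainFraction) {
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    nc <- length(idx)
    if (nc < 2L) stop("stratification error: class '", cl, "' has < 2 samples")
    nTrain <- max(1L, min(nc - 1L, round(trainFraction * nc)))
    train <- c(train, sample(idx, nTrain))
  }
  sort(train)
}

.log2choose <- function(n, k) lchoose(n, k) / log(2)
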