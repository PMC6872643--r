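#' Assemble a pipeline run configuration
#'
#' A plain validated list; the same structure can be read from YAML with
#' [readRunConfig()]. One global \code{seed} drives every stage through
#' [deriveSeed()] with the stage name, so a rerun with an identical
#' configuration reproduces identical artifacts byte for byte.
#'
#' @param input Path to a delimited feature table, or a
#'   [FeatureTable-class] object.
#' @param outDir Output directory (created if missing).
#' @param labelColumn Label column name (default \code{"phylum"}).
#' @param minClassSize Minimum class census kept by the filter (default 100).
#' @param mcfs Named list of [mcfsConfig()] arguments.
#' @param ifs Named list: \code{kMax} (default: the RI > 0 count),
#'   \code{cvFolds} (default 10).
#' @param ripper Named list of [learnRuleSet()] options.
#' @param validation Named list: \code{k} (default 25), \code{nRandom}
#'   (default 1000), \code{cvFolds} (default 10), \code{pool}.
#' @param seed Global integer seed (default 1).
#' @param skipValidation Skip the random-subset stage (default FALSE).
#' @return A list of class \code{"mcRulesRunConfig"}.
#' @export
runConfig <- function(input, outDir, labelColumn = "phylum",
                      minClassSize = 100, mcfs = list(), ifs = list(),
                      ripper = list(), validation = list(), seed = 1,
                      skipValidation = FALSE) {
  cfg <- list(input = input, outDir = outDir, labelColumn = labelColumn,
              minClassSize = minClassSize, mcfs = mcfs, ifs = ifs,
              ripper = ripper, validation = validation, seed = seed,
              skipValidation = skipValidation)
  class(cfg) <- "mcRulesRunConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror [runConfig()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A list of class \code{"mcRulesRunConfig"}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

.stage <- function(manifest, name, code) {
  tryCatch(code, error = function(e) {
    manifest$error <- list(stage = name, message = conditionMessage(e))
    .writeManifest(manifest)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

.writeManifest <- function(manifest) {
  out <- as.list(manifest)
  out$outDir <- NULL
  out$config$outDir <- NULL  # identical configs differing only in the
  out <- out[sort(names(out))]  # destination yield identical manifests
  jsonlite::write_json(out, file.path(manifest$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' Run the full workflow
#'
#' Orchestrates: load and filter the table, rank features by Monte Carlo
#' relative importance, retain the RI > 0 features, scan nested top-k subsets
#' by cross-validated multi-class MCC, learn the rule list on the optimum
#' subset, and (unless skipped) run the random-subset significance test.
#' Artifacts written to the output directory: \code{ranked.tsv},
#' \code{ifs.tsv}, \code{rules.txt}, \code{rules.json},
#' \code{confusion.tsv}, \code{report.json}, \code{validation.json} and a
#' \code{manifest.json} recording the configuration, the derived per-stage
#' seeds, stage-level counts and versions.
#'
#' @param config A \code{"mcRulesRunConfig"} from [runConfig()] /
#'   [readRunConfig()], or a path to a YAML configuration.
#' @return Invisibly, the output directory path.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "mcRulesRunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(rank = deriveSeed(config$seed, "rank"),
                ifs = deriveSeed(config$seed, "ifs"),
                rules = deriveSeed(config$seed, "rules"),
                validation = deriveSeed(config$seed, "validation"))
  manifest <- new.env(parent = emptyenv())
  manifest$outDir <- config$outDir
  cfgRecord <- config
  if (is(cfgRecord$input, "FeatureTable")) cfgRecord$input <- "<in-memory>"
  manifest$config <- unclass(cfgRecord)
  manifest$seeds <- seeds
  manifest$versions <- list(mcRules = as.character(utils::packageVersion("mcRules")),
                            R = paste(R.version$major, R.version$minor,
                                      sep = "."))

  tab <- .stage(manifest, "load", {
    if (is(config$input, "FeatureTable")) config$input else
      readFeatureTable(config$input, labelColumn = config$labelColumn)
  })
  tab <- .stage(manifest, "filter", {
    filterMinClassSize(tab, minN = config$minClassSize)
  })
  manifest$census <- as.list(classCensus(tab))

  ranked <- .stage(manifest, "rank", {
    cfg <- do.call(mcfsConfig, c(config$mcfs, list(seed = seeds$rank)))
    rankFeatures(tab, cfg)
  })
  writeRanking(ranked, file.path(config$outDir, "ranked.tsv"))
  manifest$trees <- {
    cfg <- do.call(mcfsConfig, c(config$mcfs, list(seed = seeds$rank)))
    cfg@m * cfg@t
  }
  manifest$retainedCount <- retainedCount(ranked)

  ifsRes <- .stage(manifest, "ifs", {
    kMax <- config$ifs$kMax
    if (is.null(kMax)) kMax <- max(1L, retainedCount(ranked))
    cvFolds <- config$ifs$cvFolds
    if (is.null(cvFolds)) cvFolds <- 10
    runIFS(tab, ranked, kMax = kMax, cvFolds = cvFolds, seed = seeds$ifs,
           ripperParams = config$ripper)
  })
  writeIFS(ifsRes, file.path(config$outDir, "ifs.tsv"))
  manifest$optimumK <- optimumK(ifsRes)

  rules <- .stage(manifest, "rules", {
    learnRuleSet(selectFeatures(tab, optimumFeatures(ifsRes)),
                 seed = seeds$rules,
                 folds = config$ripper$folds %||% 3,
                 minCovered = config$ripper$minCovered %||% 2,
                 optimizationPasses = config$ripper$optimizationPasses %||% 2,
                 prune = config$ripper$prune %||% TRUE)
  })
  writeRuleSet(rules, file.path(config$outDir, "rules.txt"))
  writeLines(rulesJSON(rules), file.path(config$outDir, "rules.json"))
  manifest$nRules <- length(ruleList(rules))

  optReport <- ifsRes@reports[[optimumK(ifsRes)]]
  writeConfusion(optReport, file.path(config$outDir, "confusion.tsv"))
  writeLines(reportJSON(optReport), file.path(config$outDir, "report.json"))

  if (!isTRUE(config$skipValidation)) {
    val <- .stage(manifest, "validation", {
      randomSubsetTest(
        tab, ranked,
        k = config$validation$k %||% 25,
        nRandom = config$validation$nRandom %||% 1000,
        cvFolds = config$validation$cvFolds %||% 10,
        seed = seeds$validation,
        pool = config$validation$pool %||% "all",
        ripperParams = config$ripper)
    })
    writeLines(validationJSON(val), file.path(config$outDir, "validation.json"))
    manifest$empiricalP <- val@empiricalP
  }
  .writeManifest(manifest)
  invisible(config$outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
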