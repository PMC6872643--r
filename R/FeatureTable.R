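#' Construct a FeatureTable
#'
#' @param values Numeric matrix, samples in rows and features in columns, all
#'   entries nonnegative. Row names become sample ids, column names feature
#'   names (generated when absent).
#' @param labels Class label per sample (character or factor).
#' @param source Optional character vector of per-feature source tags
#'   (\code{"ARDB"}, \code{"CARD"}, \code{"KEGG"}, \code{"VFDB"} or
#'   \code{NA}); by default parsed from a \code{"TAG: "} name prefix.
#' @return A [FeatureTable-class] object.
#' @export
#' @examples
#' v <- matrix(c(1, 0, 0, 2, 0, 1), nrow = 3,
#'             dimnames = list(NULL, c("KEGG: pathA", "f2")))
#' ft <- FeatureTable(v, labels = c("A", "A", "B"))
#' classCensus(ft)
FeatureTable <- function(values, labels, source = NULL) {
  values <- as.matrix(values)
  if (length(labels) != nrow(values)) {
    stop("need exactly one label per sample (",
         nrow(values), " samples, ", length(labels), " labels)")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("F_%04d", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("sample_%04d", seq_len(nrow(values)))
  }
  if (is.null(source)) source <- .detectSource(colnames(values))
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  se <- SummarizedExperiment(
    assays = list(counts = t(values)),
    colData = DataFrame(label = labels, row.names = rownames(values)),
    rowData = DataFrame(source = source, row.names = colnames(values)))
  new("FeatureTable", se)
}

# Source tag from a "TAG:" name prefix, restricted to the known databases
# (KEGG pathway names themselves contain colons, so only whitelisted prefixes
# count as tags).
.detectSource <- function(featureNames) {
  prefix <- trimws(sub(":.*$", "", featureNames))
  ifelse(prefix %in% c("ARDB", "CARD", "KEGG", "VFDB") &
           grepl(":", featureNames, fixed = TRUE), prefix, NA_character_)
}

#' Accessors for FeatureTable
#'
#' \code{tableValues} returns the samples-by-features count matrix;
#' \code{classLabels} the per-sample label factor; \code{classCensus} the
#' named per-class sample counts; \code{featureSources} the per-feature
#' source tags; \code{nSamples}/\code{nFeatures} the table dimensions.
#'
#' @param x A [FeatureTable-class].
#' @return See the description.
#' @name FeatureTable-accessors
#' @aliases tableValues classLabels classCensus featureSources nSamples
#'   nFeatures
#' @examples
#' ft <- FeatureTable(matrix(0:3, 2), labels = c("A", "B"))
#' tableValues(ft)
#' nFeatures(ft)
NULL

#' @rdname FeatureTable-accessors
#' @export
setMethod("tableValues", "FeatureTable", function(x) t(assay(x, "counts")))

#' @rdname FeatureTable-accessors
#' @export
setMethod("classLabels", "FeatureTable", function(x) colData(x)$label)

#' @rdname FeatureTable-accessors
#' @export
setMethod("classCensus", "FeatureTable", function(x) {
  census <- table(classLabels(x))
  stats::setNames(as.integer(census), names(census))
})

#' @rdname FeatureTable-accessors
#' @export
setMethod("featureSources", "FeatureTable", function(x) {
  stats::setNames(rowData(x)$source, rownames(x))
})

#' @rdname FeatureTable-accessors
#' @export
setMethod("nSamples", "FeatureTable", function(x) ncol(x))

#' @rdname FeatureTable-accessors
#' @export
setMethod("nFeatures", "FeatureTable", function(x) nrow(x))

setMethod("show", "FeatureTable", function(object) {
  census <- classCensus(object)
  cat("FeatureTable:", nSamples(object), "samples x", nFeatures(object),
      "features\n")
  cat("classes:",
      paste(sprintf("%s (%d)", names(census), census), collapse = ", "), "\n")
  src <- featureSources(object)
  if (any(!is.na(src))) {
    st <- table(src, useNA = "no")
    cat("feature sources:",
        paste(sprintf("%s: %d", names(st), st), collapse = ", "),
        sprintf("(untagged: %d)", sum(is.na(src))), "\n")
  }
})

#' Keep only the named features, in the given order
#'
#' @param x A [FeatureTable-class].
#' @param features Character vector of feature names or integer indices.
#' @return A [FeatureTable-class] restricted to those features.
#' @export
selectFeatures <- function(x, features) {
  if (is.character(features)) {
    missing <- setdiff(features, rownames(x))
    if (length(missing) > 0) {
      stop("unknown feature(s): ", paste(missing, collapse = ", "))
    }
  }
  x[features, ]
}

#' Read a delimited annotation-count table
#'
#' Reads a header-bearing delimited text file (tab or comma, auto-detected
#' with ties broken toward tab; optionally gzip-compressed) holding one
#' numeric column per feature plus one label column. An optional
#' \code{"sample"} column supplies sample ids.
#'
#' @param path Path to the file.
#' @param labelColumn Name of the label column (default \code{"phylum"}).
#' @param sep Field separator; \code{NULL} (default) auto-detects.
#' @return A [FeatureTable-class].
#' @export
readFeatureTable <- function(path, labelColumn = "phylum", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- function() if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  if (is.null(sep)) {
    first <- readLines(con(), n = 1L)
    nTab <- lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE)))
    nComma <- lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))
    sep <- if (nTab >= nComma) "\t" else ","
  }
  df <- utils::read.table(con(), header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!labelColumn %in% names(df)) {
    stop("format error: label column '", labelColumn, "' not found")
  }
  labels <- as.character(df[[labelColumn]])
  df[[labelColumn]] <- NULL
  sampleIds <- if ("sample" %in% names(df)) {
    ids <- as.character(df[["sample"]])
    df[["sample"]] <- NULL
    ids
  } else {
    sprintf("sample_%04d", seq_len(nrow(df)))
  }
  featNames <- names(df)
  if (anyDuplicated(featNames)) {
    stop("validation error: duplicate feature name '",
         featNames[duplicated(featNames)][1], "'")
  }
  values <- matrix(0, nrow(df), length(featNames),
                   dimnames = list(sampleIds, featNames))
  for (j in seq_along(featNames)) {
    col <- df[[j]]
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1]
      stop("validation error: non-numeric value '", col[bad],
           "' at row ", bad, ", column '", featNames[j], "'")
    }
    if (any(num < 0)) {
      bad <- which(num < 0)[1]
      stop("validation error: negative value at row ", bad,
           ", column '", featNames[j], "'")
    }
    values[, j] <- num
  }
  ft <- FeatureTable(values, labels)
  metadata(ft)$sep <- sep
  ft
}

#' Write a FeatureTable as delimited text
#'
#' Emits a \code{sample} column, one column per feature, and the label
#' column, in the table's column order. Dialect follows \code{sep} (default:
#' the dialect the table was read with, else tab). A \code{.gz} suffix
#' triggers gzip compression.
#'
#' @param x A [FeatureTable-class].
#' @param path Output path.
#' @param labelColumn Label column name (default \code{"phylum"}).
#' @param sep Field separator; default the input dialect, else tab.
#' @return Invisibly, \code{path}.
#' @export
writeFeatureTable <- function(x, path, labelColumn = "phylum", sep = NULL) {
  if (is.null(sep)) sep <- metadata(x)$sep
  if (is.null(sep)) sep <- "\t"
  df <- data.frame(sample = colnames(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(tableValues(x), check.names = FALSE))
  df[[labelColumn]] <- as.character(classLabels(x))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop classes below a minimum census
#'
#' Retains exactly the samples whose class has at least \code{minN} members
#' (the study design keeps phyla with at least 100 strains). Feature set and
#' relative sample order are unchanged; the operation is idempotent.
#'
#' @param x A [FeatureTable-class].
#' @param minN Minimum class size (default 100).
#' @return A filtered [FeatureTable-class].
#' @export
#' @examples
#' ft <- FeatureTable(matrix(0, 6, 2), labels = c("A","A","A","A","B","C"))
#' classCensus(filterMinClassSize(ft, minN = 2))
filterMinClassSize <- function(x, minN = 100) {
  stopifnot(minN >= 1)
  census <- classCensus(x)
  keepClasses <- names(census)[census >= minN]
  if (length(keepClasses) < 2L) {
    stop("degenerate dataset: fewer than 2 classes have >= ", minN, " samples")
  }
  keep <- which(as.character(classLabels(x)) %in% keepClasses)
  out <- x[, keep]
  colData(out)$label <- droplevels(colData(out)$label)
  out
}

#' Emit a class census as JSON
#'
#' @param x A [FeatureTable-class] or named census vector.
#' @return A JSON string mapping class name to sample count.
#' @export
censusJSON <- function(x) {
  census <- if (is(x, "FeatureTable")) classCensus(x) else x
  jsonlite::toJSON(as.list(census), auto_unbox = TRUE)
}
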