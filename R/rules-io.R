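# ---- human-readable rule text --------------------------------------------
# One rule per line in printed-rule-table layout:
#   (feature >= 1) and (feature <= 0) => Class
# and a final default line:
#   others => Class
# Feature names may contain spaces, colons and parentheses; the operator and
# threshold are anchored at the end of each condition.

.formatRule <- function(rule) {
  if (nrow(rule@conditions) == 0) {
    return(paste("() =>", rule@consequent))
  }
  conds <- vapply(seq_len(nrow(rule@conditions)), function(q) {
    sprintf("(%s %s %s", rule@conditions$feature[q], rule@conditions$op[q],
            format(rule@conditions$threshold[q], scientific = FALSE))
  }, character(1))
  paste0(paste(paste0(conds, ")"), collapse = " and "),
         " => ", rule@consequent)
}

#' Format a rule set as rule-table text
#'
#' @param rs A [RuleSet-class].
#' @return Character vector of lines: one per rule plus the
#'   \code{"others => <default>"} line.
#' @seealso [parseRuleText()]
#' @export
formatRuleSet <- function(rs) {
  c(vapply(rs@rules, .formatRule, character(1)),
    paste("others =>", rs@defaultClass))
}

#' Parse rule-table text into a RuleSet
#'
#' Accepts the layout written by [formatRuleSet()], tolerating the spaced
#' operator spellings \code{"> ="} / \code{"< ="} that printed tables use.
#' The \code{others} line names the default class.
#'
#' @param lines Character vector of rule lines (blank lines and \code{#}
#'   comments ignored).
#' @return A [RuleSet-class].
#' @export
#' @examples
#' parseRuleText(c("(Proteasome >= 1) => Actinobacteria",
#'                 "others => Firmicutes"))
parseRuleText <- function(lines) {
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no rules to parse")
  lines <- gsub("> =", ">=", lines, fixed = TRUE)
  lines <- gsub("< =", "<=", lines, fixed = TRUE)
  defaultCl <- NULL
  rules <- list()
  for (line in lines) {
    if (grepl("^others\\s*=>", line)) {
      defaultCl <- trimws(sub("^others\\s*=>", "", line))
      next
    }
    at <- gregexpr(" => ", line, fixed = TRUE)[[1]]
    if (at[1] == -1) stop("cannot parse rule line: ", line)
    at <- at[length(at)]  # feature names may embed the arrow text
    lhs <- trimws(substr(line, 1, at - 1))
    consequent <- trimws(substr(line, at + 4, nchar(line)))
    conds <- if (lhs == "()" || lhs == "") {
      data.frame(feature = character(0), op = character(0),
                 threshold = numeric(0), stringsAsFactors = FALSE)
    } else {
      parts <- strsplit(sub("\\)$", "", sub("^\\(", "", lhs)),
                        ") and (", fixed = TRUE)[[1]]
      parsed <- lapply(parts, function(s) {
        m <- regmatches(s, regexec("^(.*\\S)\\s*(>=|<=)\\s*(-?[0-9.]+)$", s))[[1]]
        if (length(m) == 0) stop("cannot parse condition: ", s)
        data.frame(feature = trimws(m[2]), op = m[3],
                   threshold = as.numeric(m[4]), stringsAsFactors = FALSE)
      })
      do.call(rbind, parsed)
    }
    rules[[length(rules) + 1]] <- new("Rule", conditions = conds,
                                      consequent = consequent,
                                      coverage = c(NA_real_, NA_real_))
  }
  if (is.null(defaultCl)) stop("rule text must end with an 'others =>' line")
  classes <- unique(c(vapply(rules, function(r) r@consequent, character(1)),
                      defaultCl))
  new("RuleSet", rules = rules, defaultClass = defaultCl, classes = classes)
}

#' Read a rule set from a text file
#'
#' @param path Path to a file in [formatRuleSet()] layout.
#' @return A [RuleSet-class].
#' @export
readRuleSet <- function(path) parseRuleText(readLines(path))

#' Write a rule set as text
#'
#' @param rs A [RuleSet-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeRuleSet <- function(rs, path) {
  writeLines(formatRuleSet(rs), path)
  invisible(path)
}

#' Serialize a rule set to JSON
#'
#' @param rs A [RuleSet-class].
#' @return A JSON string with the ordered rules (conditions, consequent,
#'   training coverage) and the default class.
#' @export
rulesJSON <- function(rs) {
  jsonlite::toJSON(list(
    rules = lapply(rs@rules, function(r) {
      list(conditions = r@conditions, consequent = r@consequent,
           coverage = r@coverage)
    }),
    default_class = rs@defaultClass,
    classes = rs@classes), auto_unbox = TRUE, digits = NA, na = "null")
}

#' Deserialize a rule set from JSON
#'
#' @param json A JSON string produced by [rulesJSON()].
#' @return A [RuleSet-class].
#' @export
rulesFromJSON <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  rules <- lapply(obj$rules, function(r) {
    conds <- if (length(r$conditions) == 0) {
      data.frame(feature = character(0), op = character(0),
                 threshold = numeric(0), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(r$conditions, function(cd) {
        data.frame(feature = cd$feature, op = cd$op,
                   threshold = as.numeric(cd$threshold),
                   stringsAsFactors = FALSE)
      }))
    }
    cov <- vapply(r$coverage, function(v) {
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    new("Rule", conditions = conds, consequent = r$consequent,
        coverage = cov)
  })
  new("RuleSet", rules = rules,
      defaultClass = obj$default_class,
      classes = vapply(obj$classes, identity, character(1)))
}
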