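## Dictionary-driven compliance validation. Every rule class is checked per
## row; all outcomes are findings (never exceptions). Unknown categories and
## items yield warnings -- the data standard is extended as new structures
## are deposited, so unrecognised content is not an error.

finding <- function(severity, kind, block, category = NA_character_,
                    item = NA_character_, row = NA_integer_, message) {
  data.frame(severity = severity, kind = kind, block = block,
             category = category, item = item, row = as.integer(row),
             message = message, stringsAsFactors = FALSE)
}

emptyFindings <- function() {
  data.frame(severity = character(0), kind = character(0), block = character(0),
             category = character(0), item = character(0), row = integer(0),
             message = character(0), stringsAsFactors = FALSE)
}

bindFindings <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (!length(lst)) return(emptyFindings())
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

#' ComplianceReport: result of validating a document against a dictionary
#'
#' @slot findings data.frame of findings (severity, kind, block, category,
#'   item, row, message)
#' @slot counts named integer vector of finding counts by kind
#' @slot compliant `TRUE` iff there are zero error-severity findings
#' @export
setClass("ComplianceReport",
  representation(findings = "data.frame", counts = "integer",
                 compliant = "logical"))

setValidity("ComplianceReport", function(object) {
  ok <- object@compliant == !any(object@findings$severity == "error")
  if (ok) TRUE else "compliant flag must match absence of error findings"
})

complianceReport <- function(findings) {
  counts <- vapply(FINDING_KINDS, function(k) sum(findings$kind == k), integer(1))
  new("ComplianceReport", findings = findings, counts = counts,
      compliant = !any(findings$severity == "error"))
}

#' @rdname validateDocument
#' @param report a [ComplianceReport-class]
#' @export
isCompliant <- function(report) report@compliant

#' @rdname validateDocument
#' @export
complianceFindings <- function(report) report@findings

#' @rdname validateDocument
#' @export
findingCounts <- function(report) report@counts

setMethod("show", "ComplianceReport", function(object) {
  nerr <- sum(object@findings$severity == "error")
  nwarn <- sum(object@findings$severity == "warning")
  cat(sprintf("ComplianceReport: %s (%d error(s), %d warning(s))\n",
              if (object@compliant) "compliant" else "NOT compliant",
              nerr, nwarn))
  for (k in names(object@counts))
    if (object@counts[[k]] > 0) cat(sprintf("  %s: %d\n", k, object@counts[[k]]))
})

#' Render a compliance report as text or JSON
#' @param report a [ComplianceReport-class]
#' @return `reportToText`: character vector of lines; `reportToJson`: JSON string
#' @export
reportToText <- function(report) {
  head <- sprintf("%s: %d finding(s)",
                  if (report@compliant) "COMPLIANT" else "NOT COMPLIANT",
                  nrow(report@findings))
  lines <- vapply(seq_len(nrow(report@findings)), function(i) {
    f <- report@findings[i, ]
    sprintf("[%s] %s at %s/%s%s%s: %s", f$severity, f$kind, f$block,
            ifelse(is.na(f$category), "-", f$category),
            ifelse(is.na(f$item), "", paste0(".", f$item)),
            ifelse(is.na(f$row), "", sprintf(" row %d", f$row)), f$message)
  }, character(1))
  c(head, lines)
}

#' @rdname reportToText
#' @export
reportToJson <- function(report) {
  jsonlite::toJSON(list(compliant = report@compliant,
                        counts = as.list(report@counts),
                        findings = report@findings),
                   auto_unbox = TRUE, dataframe = "rows", pretty = TRUE)
}

typeOk <- function(value, type) {
  switch(type,
    int = grepl("^[+-]?[0-9]+$", value),
    float = grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", value),
    code = grepl("^[^ \t]+$", value),
    text = TRUE,
    `yyyy-mm-dd` = grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", value) &&
      !is.na(suppressWarnings(as.Date(value, "%Y-%m-%d"))),
    TRUE)
}

rangeOk <- function(x, range) {
  lo <- if (range$min_open) x > range$min else x >= range$min
  hi <- if (range$max_open) x < range$max else x <= range$max
  lo && hi
}

validateCategoryAgainstDef <- function(cat, cdef, blockName, parentValues) {
  out <- list()
  add <- function(...) out[[length(out) + 1L]] <<- finding(...)
  present <- itemNames(cat)
  nr <- categoryRowCount(cat)

  for (item in present)
    if (is.null(cdef$items[[item]]))
      add("warning", "UNKNOWN_ITEM", blockName, cdef$name, item, NA,
          sprintf("item '%s' is not defined in the dictionary", item))

  for (idef in cdef$items) {
    item <- idef$name
    j <- match(item, present)
    if (is.na(j)) {
      if (idef$mandatory)
        add("error", "MISSING_MANDATORY_ITEM", blockName, cdef$name, item, NA,
            sprintf("mandatory item '%s' is absent", item))
      next
    }
    vals <- cat@values[, j]; flags <- cat@flags[, j]
    for (i in seq_len(nr)) {
      if (flags[[i]] != CIF_TEXT) {
        if (idef$mandatory)
          add("error", "MISSING_MANDATORY_ITEM", blockName, cdef$name, item, i,
              sprintf("mandatory item '%s' is %s", item,
                      if (flags[[i]] == CIF_UNKNOWN) "unknown (?)" else "inapplicable (.)"))
        next
      }
      v <- vals[[i]]
      if (!typeOk(v, idef$type)) {
        add("error", "BAD_TYPE", blockName, cdef$name, item, i,
            sprintf("value '%s' is not a valid %s", v, idef$type))
        next
      }
      if (!is.null(idef$enumeration) && !v %in% idef$enumeration)
        add("error", "ENUM_VIOLATION", blockName, cdef$name, item, i,
            sprintf("value '%s' not in {%s}", v,
                    paste(idef$enumeration, collapse = ", ")))
      if (!is.null(idef$range) && idef$type %in% c("int", "float")) {
        x <- suppressWarnings(as.numeric(v))
        if (!is.na(x) && !rangeOk(x, idef$range))
          add("error", "RANGE_VIOLATION", blockName, cdef$name, item, i,
              sprintf("value %s outside %s%s, %s%s", v,
                      if (idef$range$min_open) "(" else "[", idef$range$min,
                      idef$range$max, if (idef$range$max_open) ")" else "]"))
      }
      if (!is.null(idef$parent)) {
        pv <- parentValues(idef$parent[[1]], idef$parent[[2]])
        if (!v %in% pv)
          add("error", "PARENT_MISSING", blockName, cdef$name, item, i,
              sprintf("child value '%s' has no parent in %s.%s", v,
                      idef$parent[[1]], idef$parent[[2]]))
      }
    }
  }

  if (length(cdef$key_items) && all(cdef$key_items %in% present)) {
    jj <- match(cdef$key_items, present)
    tuples <- apply(cbind(cat@flags[, jj, drop = FALSE],
                          cat@values[, jj, drop = FALSE]), 1,
                    paste, collapse = "\r")
    dup <- duplicated(tuples)
    for (i in which(dup))
      add("error", "DUPLICATE_KEY", blockName, cdef$name,
          paste(cdef$key_items, collapse = ","), i,
          sprintf("key tuple duplicated at row %d", i))
  }
  out
}

#' Validate a document against a dictionary
#'
#' Checks, per row: presence of mandatory categories and items (`?`/`.`
#' sentinels do not satisfy a mandatory item), value types, controlled
#' vocabularies, numeric boundary conditions, parent--child relationships
#' between data items, and key-tuple uniqueness. Categories and items absent
#' from the dictionary yield warnings, not errors.
#'
#' @param doc a parsed [CifDocument-class]
#' @param dict a [DictionaryModel-class]
#' @return a [ComplianceReport-class]
#' @export
validateDocument <- function(doc, dict) {
  out <- list()
  for (blk in doc@blocks) {
    cats <- blk@categories
    parentValues <- function(pcat, pitem) {
      pc <- cats[[pcat]]
      if (is.null(pc)) return(character(0))
      j <- match(pitem, itemNames(pc))
      if (is.na(j)) return(character(0))
      pc@values[pc@flags[, j] == CIF_TEXT, j]
    }
    for (cdef in dict@categories)
      if (cdef$mandatory &&
          (is.null(cats[[cdef$name]]) || categoryRowCount(cats[[cdef$name]]) == 0L))
        out[[length(out) + 1L]] <- finding(
          "error", "MISSING_MANDATORY_CATEGORY", blk@name, cdef$name, NA, NA,
          sprintf("mandatory category '%s' is absent", cdef$name))
    for (cat in cats) {
      cdef <- dict@categories[[cat@name]]
      if (is.null(cdef)) {
        out[[length(out) + 1L]] <- finding(
          "warning", "UNKNOWN_CATEGORY", blk@name, cat@name, NA, NA,
          sprintf("category '%s' is not defined in the dictionary", cat@name))
        next
      }
      out <- c(out, validateCategoryAgainstDef(cat, cdef, blk@name, parentValues))
    }
  }
  complianceReport(bindFindings(out))
}

## Validate a standalone tabular payload against one category's rules
## (mandatory items, types, vocabularies, ranges, keys). Parent links cannot
## be resolved without a document context and are skipped. Used by the
## harvesting workflow's metadata sections.
validateCategoryPayload <- function(df, category, dict, blockName = "payload") {
  cdef <- dict@categories[[category]]
  if (is.null(cdef))
    stop("dictionary defines no category '", category, "'", call. = FALSE)
  cdefNoParent <- cdef
  for (nm in names(cdefNoParent$items)) cdefNoParent$items[[nm]]$parent <- NULL
  rows <- lapply(df, function(col) ifelse(is.na(col), NA_character_,
                                          as.character(col)))
  cat <- cifCategory(category, rows)
  bindFindings(validateCategoryAgainstDef(cat, cdefNoParent, blockName,
                                          function(...) character(0)))
}
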