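## Syntax-level mmCIF containers.  Values are kept as text at this layer;
## typing is the dictionary layer's job.  Each category carries, alongside its
## character matrix of values, an integer matrix of sentinel flags so that the
## STAR "unknown" (`?`) and "inapplicable" (`.`) markers are distinguished from
## literal text "?" / "." (which the format writes quoted).

#' @importFrom methods new validObject is slot slot<- setClass setGeneric
#'   setMethod setValidity show
NULL

## Sentinel flag codes used in the @flags matrix of a CifCategory.
CIF_TEXT <- 0L
CIF_UNKNOWN <- 1L
CIF_INAPPLICABLE <- 2L

#' CifCategory: one mmCIF category (a named table of items)
#'
#' A category holds an ordered set of item (column) names and a row-major
#' table of values. Values are stored as a character matrix plus a parallel
#' integer flag matrix distinguishing ordinary text from the `?` (unknown)
#' and `.` (inapplicable) sentinels of the STAR syntax.
#'
#' @slot name lowercase category identifier (`[a-z0-9_]+`)
#' @slot items character vector of item identifiers, unique, in file order
#' @slot values character matrix, one column per item; `NA` where flagged
#' @slot flags integer matrix of the same shape: 0 text, 1 unknown, 2 inapplicable
#' @export
setClass("CifCategory",
  representation(name = "character", items = "character",
                 values = "matrix", flags = "matrix"))

setValidity("CifCategory", function(object) {
  msgs <- character(0)
  if (length(object@name) != 1L || !grepl("^[a-z0-9_]+$", object@name))
    msgs <- c(msgs, "category name must be a single [a-z0-9_]+ identifier")
  if (anyDuplicated(object@items))
    msgs <- c(msgs, "item names must be unique within a category")
  if (ncol(object@values) != length(object@items))
    msgs <- c(msgs, "value matrix must have one column per item")
  if (!identical(dim(object@values), dim(object@flags)))
    msgs <- c(msgs, "values and flags must have identical dimensions")
  if (length(object@flags) && !all(object@flags %in% 0:2))
    msgs <- c(msgs, "flags must be 0 (text), 1 (unknown) or 2 (inapplicable)")
  if (length(msgs)) msgs else TRUE
})

#' CifBlock: one `data_` block of an mmCIF file
#'
#' @slot name block identifier (text after `data_`)
#' @slot categories named list of [CifCategory-class] objects, unique names
#' @slot frames named list of CifBlock objects holding STAR save frames
#'   (used only by dictionary files; ordinary entries have none)
#' @export
setClass("CifBlock",
  representation(name = "character", categories = "list", frames = "list"))

setValidity("CifBlock", function(object) {
  msgs <- character(0)
  if (length(object@name) != 1L) msgs <- c(msgs, "block needs exactly one name")
  nm <- vapply(object@categories, function(x) x@name, character(1))
  if (anyDuplicated(nm)) msgs <- c(msgs, "category names must be unique in a block")
  if (!identical(unname(names(object@categories)), unname(nm)) &&
      length(object@categories))
    msgs <- c(msgs, "categories list must be named by category name")
  if (length(msgs)) msgs else TRUE
})

#' CifDocument: an ordered collection of data blocks
#'
#' @slot blocks list of [CifBlock-class] objects with unique names, in file order
#' @export
setClass("CifDocument", representation(blocks = "list"))

setValidity("CifDocument", function(object) {
  nm <- vapply(object@blocks, function(x) x@name, character(1))
  if (anyDuplicated(nm)) "block names must be unique" else TRUE
})

#' Construct a CifCategory
#'
#' @param name category name (lowercase identifier).
#' @param rows a data.frame or named list of equal-length character vectors,
#'   one element per item. Use [cifUnknown()] / [cifInapplicable()] cell markers
#'   or pass `flags` explicitly; plain `NA` is treated as unknown (`?`).
#' @param flags optional integer matrix of sentinel flags (0/1/2).
#' @return a [CifCategory-class]
#' @export
cifCategory <- function(name, rows, flags = NULL) {
  if (is.data.frame(rows)) rows <- as.list(rows)
  items <- names(rows)
  n <- if (length(rows)) length(rows[[1]]) else 0L
  vals <- matrix(NA_character_, nrow = n, ncol = length(items))
  for (j in seq_along(rows)) vals[, j] <- as.character(rows[[j]])
  if (is.null(flags)) {
    flags <- matrix(CIF_TEXT, nrow = n, ncol = length(items))
    flags[is.na(vals)] <- CIF_UNKNOWN
  }
  vals[flags != CIF_TEXT] <- NA_character_
  new("CifCategory", name = name, items = items, values = vals, flags = flags)
}

#' Construct a CifBlock
#' @param name block name
#' @param categories list of [CifCategory-class] objects
#' @param frames list of save-frame [CifBlock-class] objects (dictionaries only)
#' @export
cifBlock <- function(name, categories = list(), frames = list()) {
  names(categories) <- vapply(categories, function(x) x@name, character(1))
  if (length(frames))
    names(frames) <- vapply(frames, function(x) x@name, character(1))
  new("CifBlock", name = name, categories = categories, frames = frames)
}

#' Construct a CifDocument
#' @param blocks list of [CifBlock-class] objects
#' @export
cifDocument <- function(blocks = list()) new("CifDocument", blocks = blocks)

#' Sentinel markers for mmCIF cells
#'
#' `cifUnknown()` and `cifInapplicable()` return the string forms `?` and `.`;
#' they are interpreted by the writer only through the flags matrix, so use
#' [setCifCell()] or the `flags` argument of [cifCategory()] to place them.
#' @return marker string
#' @export
cifUnknown <- function() "?"

#' @rdname cifUnknown
#' @export
cifInapplicable <- function() "."

## ---- accessors -------------------------------------------------------------

#' Accessors for CIF containers
#'
#' Small accessor family: block/category lookup by name, item names, row
#' counts and cell access. These are the supported way to inspect parsed
#' documents; slots are internal.
#'
#' @param doc a [CifDocument-class]
#' @param name block or category name
#' @return `cifBlockNames`: character vector of block names.
#' @export
cifBlockNames <- function(doc) vapply(doc@blocks, function(b) b@name, character(1))

#' @rdname cifBlockNames
#' @export
getBlock <- function(doc, name) {
  i <- match(name, cifBlockNames(doc))
  if (is.na(i)) stop("no block named '", name, "'", call. = FALSE)
  doc@blocks[[i]]
}

#' @rdname cifBlockNames
#' @param block a [CifBlock-class]
#' @export
categoryNames <- function(block) names(block@categories)

#' @rdname cifBlockNames
#' @export
getCategory <- function(block, name) {
  cat <- block@categories[[name]]
  if (is.null(cat)) stop("no category named '", name, "'", call. = FALSE)
  cat
}

#' @rdname cifBlockNames
#' @param x a [CifCategory-class]
#' @export
itemNames <- function(x) x@items

#' @rdname cifBlockNames
#' @export
categoryRowCount <- function(x) nrow(x@values)

#' Read a category as a data.frame of text values
#'
#' Unknown and inapplicable cells come back as `NA` with the distinction
#' available from [cifFlags()].
#' @param x a [CifCategory-class]
#' @return data.frame of character columns
#' @export
categoryTable <- function(x) {
  df <- as.data.frame(x@values, stringsAsFactors = FALSE)
  names(df) <- x@items
  df
}

#' @rdname categoryTable
#' @export
cifFlags <- function(x) {
  f <- x@flags
  dimnames(f) <- list(NULL, x@items)
  f
}

#' Set one cell of a category, including sentinel placement
#'
#' @param x a [CifCategory-class]
#' @param row row index
#' @param item item name
#' @param value character value, or ignored when `flag` is not 0
#' @param flag 0 text, 1 unknown (`?`), 2 inapplicable (`.`)
#' @return modified [CifCategory-class]
#' @export
setCifCell <- function(x, row, item, value, flag = CIF_TEXT) {
  j <- match(item, x@items)
  if (is.na(j)) stop("no item '", item, "' in category ", x@name, call. = FALSE)
  x@values[row, j] <- if (flag == CIF_TEXT) value else NA_character_
  x@flags[row, j] <- as.integer(flag)
  x
}

setMethod("show", "CifCategory", function(object) {
  cat(sprintf("CifCategory '%s': %d item(s), %d row(s)\n",
              object@name, length(object@items), nrow(object@values)))
})

setMethod("show", "CifBlock", function(object) {
  cat(sprintf("CifBlock '%s': %d categories%s\n", object@name,
              length(object@categories),
              if (length(object@frames))
                sprintf(", %d save frames", length(object@frames)) else ""))
})

setMethod("show", "CifDocument", function(object) {
  cat(sprintf("CifDocument with %d block(s)\n", length(object@blocks)))
  for (b in object@blocks)
    cat(sprintf("  data_%s: %s\n", b@name,
                paste(categoryNames(b), collapse = ", ")))
})
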