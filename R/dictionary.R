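## Machine-readable dictionary: item/category definitions driving compliance
## validation. The file format is a small mmCIF dialect using STAR save
## frames -- one frame per category (`save_<cat>`, with `_category.*` and
## `_category_key.item`) and one per item (`save__<cat>.<item>`, with
## `_item.*`, optional `_item_enumeration.value` loop, `_item_range.*` and
## `_item_linked.parent_*`). See the shipped mini dictionary in
## inst/extdata/ for a complete example.

FINDING_KINDS <- c("MISSING_MANDATORY_CATEGORY", "MISSING_MANDATORY_ITEM",
                   "BAD_TYPE", "ENUM_VIOLATION", "RANGE_VIOLATION",
                   "PARENT_MISSING", "DUPLICATE_KEY", "UNKNOWN_CATEGORY",
                   "UNKNOWN_ITEM")

ITEM_TYPES <- c("int", "float", "text", "code", "yyyy-mm-dd")

#' DictionaryModel: machine-readable category/item definitions
#'
#' @slot title dictionary title
#' @slot version dictionary version string
#' @slot categories named list; each element holds `name`, `mandatory`,
#'   `key_items` and `items` (a named list of item definitions with `type`,
#'   `mandatory`, `enumeration`, `range`, `parent`, `description`)
#' @export
setClass("DictionaryModel",
  representation(title = "character", version = "character",
                 categories = "list"))

setValidity("DictionaryModel", function(object) {
  msgs <- character(0)
  for (cdef in object@categories) {
    if (!all(cdef$key_items %in% names(cdef$items)))
      msgs <- c(msgs, sprintf("category '%s': key items must be defined items",
                              cdef$name))
    for (idef in cdef$items) {
      if (!is.null(idef$enumeration) && !is.null(idef$range))
        msgs <- c(msgs, sprintf("item '%s.%s': enumeration and range are mutually exclusive",
                                cdef$name, idef$name))
      if (!is.null(idef$parent)) {
        pc <- object@categories[[idef$parent[[1]]]]
        if (is.null(pc) || !idef$parent[[2]] %in% names(pc$items))
          msgs <- c(msgs, sprintf("item '%s.%s': parent link to undefined item '%s.%s'",
                                  cdef$name, idef$name,
                                  idef$parent[[1]], idef$parent[[2]]))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "DictionaryModel", function(object) {
  nitems <- sum(vapply(object@categories, function(c) length(c$items), integer(1)))
  cat(sprintf("DictionaryModel '%s' v%s: %d categories, %d item definitions\n",
              object@title, object@version, length(object@categories), nitems))
})

#' @rdname loadDictionary
#' @param dict a [DictionaryModel-class]
#' @export
dictionaryCategories <- function(dict) names(dict@categories)

frameScalar <- function(frame, category, item) {
  cat <- frame@categories[[category]]
  if (is.null(cat)) return(NA_character_)
  j <- match(item, cat@items)
  if (is.na(j) || nrow(cat@values) < 1L) return(NA_character_)
  if (cat@flags[1L, j] != CIF_TEXT) return(NA_character_)
  cat@values[1L, j]
}

frameColumn <- function(frame, category, item) {
  cat <- frame@categories[[category]]
  if (is.null(cat)) return(character(0))
  j <- match(item, cat@items)
  if (is.na(j)) return(character(0))
  cat@values[cat@flags[, j] == CIF_TEXT, j]
}

yes <- function(x) !is.na(x) && tolower(x) == "yes"

#' Load a validation dictionary
#'
#' Reads the documented save-frame dictionary dialect and resolves all
#' cross-references. Duplicate definitions and parent links to undefined
#' items are load errors.
#'
#' @param text dictionary source text, or `NULL` when `file` given
#' @param file path to a dictionary file
#' @return a [DictionaryModel-class]
#' @export
loadDictionary <- function(text = NULL, file = NULL) {
  doc <- parseCif(text = text, file = file)
  if (!length(doc@blocks))
    return(new("DictionaryModel", title = "empty", version = "0", categories = list()))
  blk <- doc@blocks[[1L]]
  title <- frameScalar(blk, "dictionary", "title")
  version <- frameScalar(blk, "dictionary", "version")
  categories <- list()
  itemFrames <- list()
  for (fr in blk@frames) {
    if ("category" %in% names(fr@categories)) {
      nm <- frameScalar(fr, "category", "name")
      if (is.na(nm)) stop("category frame without _category.name", call. = FALSE)
      if (!is.null(categories[[nm]]))
        stop("duplicate category definition '", nm, "'", call. = FALSE)
      categories[[nm]] <- list(name = nm,
                               mandatory = yes(frameScalar(fr, "category", "mandatory")),
                               key_items = frameColumn(fr, "category_key", "item"),
                               items = list())
    } else if ("item" %in% names(fr@categories)) {
      itemFrames[[length(itemFrames) + 1L]] <- fr
    } else {
      stop("save frame '", fr@name, "' is neither a category nor an item definition",
           call. = FALSE)
    }
  }
  for (fr in itemFrames) {
    catName <- frameScalar(fr, "item", "category")
    itemName <- frameScalar(fr, "item", "name")
    if (is.na(catName) || is.na(itemName))
      stop("item frame '", fr@name, "' lacks _item.category/_item.name", call. = FALSE)
    if (is.null(categories[[catName]]))
      stop("item '", catName, ".", itemName,
           "' defined for undeclared category '", catName, "'", call. = FALSE)
    if (!is.null(categories[[catName]]$items[[itemName]]))
      stop("duplicate item definition '", catName, ".", itemName, "'", call. = FALSE)
    type <- frameScalar(fr, "item", "type")
    if (!type %in% ITEM_TYPES)
      stop("item '", catName, ".", itemName, "': unknown type '", type, "'",
           call. = FALSE)
    enum <- frameColumn(fr, "item_enumeration", "value")
    range <- NULL
    if ("item_range" %in% names(fr@categories)) {
      mn <- frameScalar(fr, "item_range", "min")
      mx <- frameScalar(fr, "item_range", "max")
      range <- list(min = if (is.na(mn)) -Inf else as.numeric(mn),
                    max = if (is.na(mx)) Inf else as.numeric(mx),
                    min_open = yes(frameScalar(fr, "item_range", "min_open")),
                    max_open = yes(frameScalar(fr, "item_range", "max_open")))
    }
    parent <- NULL
    pc <- frameScalar(fr, "item_linked", "parent_category")
    if (!is.na(pc)) parent <- c(pc, frameScalar(fr, "item_linked", "parent_item"))
    categories[[catName]]$items[[itemName]] <- list(
      name = itemName, category = catName, type = type,
      mandatory = yes(frameScalar(fr, "item", "mandatory")),
      enumeration = if (length(enum)) enum else NULL,
      range = range, parent = parent,
      description = frameScalar(fr, "item", "description"))
  }
  dict <- new("DictionaryModel",
              title = if (is.na(title)) "untitled" else title,
              version = if (is.na(version)) "0" else version,
              categories = categories)
  validObject(dict)  # resolves parent links; errors name the broken link
  dict
}

#' The bundled mini validation dictionary
#'
#' A self-contained dictionary covering every category of the entry layout,
#' with the types, controlled vocabularies, boundary conditions and
#' parent--child relationships used throughout the package. It is a minimal
#' synthetic stand-in for a full archive dictionary, not a replica of one.
#'
#' @return a [DictionaryModel-class]
#' @export
ihmDictionary <- function() {
  loadDictionary(file = system.file("extdata", "mini_ihm_dict.cif",
                                    package = "ihmforge", mustWork = TRUE))
}
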