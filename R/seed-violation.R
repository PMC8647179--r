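## Controlled corruption of a compliant document: injects exactly one
## violation of a requested kind at a pseudo-randomly chosen eligible
## location and returns the finding the validator is expected to report.
## Locations are chosen so that the mutation cannot trip any other rule
## (e.g. the mandatory category removed has no child links pointing at it).

## eligible (category, item) cells per kind, against the mini dictionary;
## only categories present in the document are considered
.seedSpots <- list(
  MISSING_MANDATORY_CATEGORY = c("entry", "audit_author"),
  MISSING_MANDATORY_ITEM = list(
    c("citation", "title"), c("citation", "journal"),
    c("audit_author", "name"), c("software", "classification"),
    c("protocol_step", "method_name")),
  BAD_TYPE = list(
    c("atom_site", "cartn_x"), c("atom_site", "cartn_y"),
    c("atom_site", "cartn_z"), c("sphere_site", "cartn_x"),
    c("sphere_site", "cartn_z"), c("fit_metric", "metric_value")),
  ENUM_VIOLATION = list(
    c("crosslink_restraint", "conditionality", "some"),
    c("dataset", "data_type", "FOO"),
    c("representation_segment", "mode", "fuzzy"),
    c("protocol_step", "multi_scale", "maybe"),
    c("entity", "type", "plasma")),
  RANGE_VIOLATION = list(
    c("sphere_site", "radius", "-1.0"),
    c("crosslink_restraint", "threshold_a", "-5"),
    c("state", "population_fraction", "1.5"),
    c("ensemble", "num_models_total", "-3")),
  PARENT_MISSING = list(
    c("atom_site", "asym_id"), c("sphere_site", "asym_id"),
    c("model_group_link", "model_id"), c("crosslink_restraint", "dataset_id"),
    c("ensemble", "group_id")),
  DUPLICATE_KEY = c("software", "citation", "audit_author", "model_group"),
  UNKNOWN_CATEGORY = "zz_custom",
  UNKNOWN_ITEM = c("software", "citation", "model_group", "dataset")
)

#' Inject exactly one dictionary violation into a document
#'
#' Given a document that is compliant against the bundled mini dictionary,
#' corrupts it with exactly one violation of the requested kind at a
#' pseudo-randomly chosen eligible location, and returns the finding the
#' validator must report (kind and exact location).
#'
#' @param doc a compliant [CifDocument-class]
#' @param kind one of the validator finding kinds (see `FINDING_KINDS`)
#' @param seed integer seed for the location choice
#' @return `list(doc=, expected=)` where `expected` is a one-row finding
#'   data.frame (severity, kind, block, category, item, row)
#' @export
seedViolation <- function(doc, kind, seed = 1L) {
  kind <- match.arg(kind, FINDING_KINDS)
  blk <- doc@blocks[[1L]]
  cats <- blk@categories
  pickFrom <- function(pool, present) {
    keep <- Filter(function(p) p[[1]] %in% present, pool)
    if (!length(keep))
      stop("no eligible location for kind ", kind, call. = FALSE)
    keep[[sample.int(length(keep), 1L)]]
  }
  setCell <- function(cat, item, row, value, flag = CIF_TEXT) {
    cats[[cat]] <<- setCifCell(cats[[cat]], row, item, value, flag)
  }
  expected <- NULL

  withSeed(seed, switch(kind,
    MISSING_MANDATORY_CATEGORY = {
      pool <- intersect(.seedSpots[[kind]], names(cats))
      if (!length(pool)) stop("no eligible location for kind ", kind, call. = FALSE)
      target <- pool[[sample.int(length(pool), 1L)]]
      cats[[target]] <- NULL
      expected <- finding("error", kind, blk@name, target, NA, NA,
                          "mandatory category removed")
    },
    MISSING_MANDATORY_ITEM = {
      spot <- pickFrom(.seedSpots[[kind]], names(cats))
      row <- sample.int(categoryRowCount(cats[[spot[[1]]]]), 1L)
      setCell(spot[[1]], spot[[2]], row, NA, CIF_UNKNOWN)
      expected <- finding("error", kind, blk@name, spot[[1]], spot[[2]], row,
                          "mandatory cell blanked")
    },
    BAD_TYPE = {
      spot <- pickFrom(.seedSpots[[kind]], names(cats))
      row <- sample.int(categoryRowCount(cats[[spot[[1]]]]), 1L)
      setCell(spot[[1]], spot[[2]], row, "not-a-number")
      expected <- finding("error", kind, blk@name, spot[[1]], spot[[2]], row,
                          "numeric cell corrupted")
    },
    ENUM_VIOLATION = {
      spot <- pickFrom(.seedSpots[[kind]], names(cats))
      row <- sample.int(categoryRowCount(cats[[spot[[1]]]]), 1L)
      setCell(spot[[1]], spot[[2]], row, spot[[3]])
      expected <- finding("error", kind, blk@name, spot[[1]], spot[[2]], row,
                          "value outside controlled vocabulary")
    },
    RANGE_VIOLATION = {
      spot <- pickFrom(.seedSpots[[kind]], names(cats))
      row <- sample.int(categoryRowCount(cats[[spot[[1]]]]), 1L)
      setCell(spot[[1]], spot[[2]], row, spot[[3]])
      expected <- finding("error", kind, blk@name, spot[[1]], spot[[2]], row,
                          "value outside boundary condition")
    },
    PARENT_MISSING = {
      spot <- pickFrom(.seedSpots[[kind]], names(cats))
      row <- sample.int(categoryRowCount(cats[[spot[[1]]]]), 1L)
      setCell(spot[[1]], spot[[2]], row, "zz_orphan")
      expected <- finding("error", kind, blk@name, spot[[1]], spot[[2]], row,
                          "child value rewritten to an unused id")
    },
    DUPLICATE_KEY = {
      pool <- intersect(.seedSpots[[kind]], names(cats))
      if (!length(pool)) stop("no eligible location for kind ", kind, call. = FALSE)
      target <- pool[[sample.int(length(pool), 1L)]]
      cat <- cats[[target]]
      row <- sample.int(nrow(cat@values), 1L)
      cat@values <- rbind(cat@values, cat@values[row, , drop = FALSE])
      cat@flags <- rbind(cat@flags, cat@flags[row, , drop = FALSE])
      cats[[target]] <- cat
      keyItems <- switch(target, software = "id", citation = "id",
                         audit_author = "ordinal", model_group = "id")
      expected <- finding("error", kind, blk@name, target, keyItems,
                          nrow(cat@values), "key tuple duplicated")
    },
    UNKNOWN_CATEGORY = {
      nm <- .seedSpots[[kind]]
      cats[[nm]] <- cifCategory(nm, list(x = "1"))
      expected <- finding("warning", kind, blk@name, nm, NA, NA,
                          "category not in dictionary")
    },
    UNKNOWN_ITEM = {
      pool <- intersect(.seedSpots[[kind]], names(cats))
      target <- pool[[sample.int(length(pool), 1L)]]
      cat <- cats[[target]]
      cat@items <- c(cat@items, "zz_extra")
      cat@values <- cbind(cat@values, rep("1", nrow(cat@values)))
      cat@flags <- cbind(cat@flags, rep(CIF_TEXT, nrow(cat@flags)))
      cats[[target]] <- cat
      expected <- finding("warning", kind, blk@name, target, "zz_extra", NA,
                          "item not in dictionary")
    }))

  newBlk <- cifBlock(blk@name, unname(cats), blk@frames)
  list(doc = cifDocument(c(list(newBlk), doc@blocks[-1L])), expected = expected)
}
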