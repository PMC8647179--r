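## Semantic document equality: ignores quoting style, whitespace, comments,
## item order within a category and category order within a block; respects
## block order, row order and value content including the unknown (`?`) vs
## inapplicable (`.`) distinction.

describeCell <- function(val, flag) {
  if (flag == CIF_UNKNOWN) return("? (unknown)")
  if (flag == CIF_INAPPLICABLE) return(". (inapplicable)")
  sprintf("'%s'", val)
}

categoryDiff <- function(blockName, a, b) {
  if (!setequal(a@items, b@items))
    return(sprintf("block '%s' category '%s': item sets differ (%s vs %s)",
                   blockName, a@name,
                   paste(sort(a@items), collapse = ","),
                   paste(sort(b@items), collapse = ",")))
  if (nrow(a@values) != nrow(b@values))
    return(sprintf("block '%s' category '%s': %d vs %d rows",
                   blockName, a@name, nrow(a@values), nrow(b@values)))
  perm <- match(a@items, b@items)
  for (i in seq_len(nrow(a@values))) {
    for (j in seq_along(a@items)) {
      fa <- a@flags[i, j]; fb <- b@flags[i, perm[j]]
      va <- a@values[i, j]; vb <- b@values[i, perm[j]]
      if (fa != fb || (fa == CIF_TEXT && !identical(va, vb)))
        return(sprintf("block '%s' category '%s' item '%s' row %d: %s vs %s",
                       blockName, a@name, a@items[[j]], i,
                       describeCell(va, fa), describeCell(vb, fb)))
    }
  }
  NULL
}

## Zero-row categories are not representable in the format and are ignored.
liveCategories <- function(blk) {
  keep <- vapply(blk@categories, function(x) nrow(x@values) > 0L, logical(1))
  blk@categories[keep]
}

blockDiff <- function(a, b) {
  ca <- liveCategories(a); cb <- liveCategories(b)
  if (!setequal(names(ca), names(cb)))
    return(sprintf("block '%s': category sets differ (%s vs %s)", a@name,
                   paste(sort(names(ca)), collapse = ","),
                   paste(sort(names(cb)), collapse = ",")))
  for (nm in names(ca)) {
    d <- categoryDiff(a@name, ca[[nm]], cb[[nm]])
    if (!is.null(d)) return(d)
  }
  if (!setequal(names(a@frames), names(b@frames)))
    return(sprintf("block '%s': save frame sets differ", a@name))
  for (nm in names(a@frames)) {
    d <- blockDiff(a@frames[[nm]], b@frames[[nm]])
    if (!is.null(d)) return(d)
  }
  NULL
}

#' First semantic difference between two CIF documents
#'
#' @param a,b [CifDocument-class] objects
#' @return `NULL` when semantically equal, otherwise a one-line description
#'   of the first difference found (naming block, category, item and row).
#' @export
cifDiff <- function(a, b) {
  na <- cifBlockNames(a); nb <- cifBlockNames(b)
  if (length(na) != length(nb))
    return(sprintf("%d vs %d blocks", length(na), length(nb)))
  if (!identical(na, nb))
    return(sprintf("block order/names differ: [%s] vs [%s]",
                   paste(na, collapse = ","), paste(nb, collapse = ",")))
  for (i in seq_along(a@blocks)) {
    d <- blockDiff(a@blocks[[i]], b@blocks[[i]])
    if (!is.null(d)) return(d)
  }
  NULL
}

#' Are two CIF documents semantically equal?
#'
#' Equality ignores quoting style, whitespace, comments, item order within a
#' category and category order within a block; it respects block order, row
#' order and value content, and distinguishes the unknown (`?`) from the
#' inapplicable (`.`) sentinel.
#'
#' @param a,b [CifDocument-class] objects
#' @return `TRUE` or `FALSE`; when `FALSE`, attribute `"difference"` holds a
#'   description of the first difference.
#' @export
cifEquals <- function(a, b) {
  d <- cifDiff(a, b)
  if (is.null(d)) TRUE else structure(FALSE, difference = d)
}
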