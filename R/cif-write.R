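## Conservative mmCIF writer. Values that need protection are quoted; values
## containing newlines or un-quotable quote combinations use semicolon fences.
## One-row categories are written key-value style, multi-row categories as
## loops. Output line length is not limited.

needsQuoting <- function(value) {
  if (!nzchar(value)) return(TRUE)
  if (grepl("[ \t]", value)) return(TRUE)
  first <- substr(value, 1L, 1L)
  if (first %in% c("_", "#", "'", "\"", ";", "$", "[", "]")) return(TRUE)
  if (value %in% c("?", ".")) return(TRUE)
  if (grepl("^(data|loop|save|stop|global)_", value, ignore.case = TRUE)) return(TRUE)
  FALSE
}

## Can `value` live inside quotes of char q? The closing rule is
## quote-followed-by-whitespace, so an internal q+whitespace sequence breaks it.
quotable <- function(value, q) !grepl(paste0(q, "[ \t]"), value, fixed = FALSE)

## Render one cell. Returns list(text=, fenced=logical).
renderValue <- function(value, flag) {
  if (flag == CIF_UNKNOWN) return(list(text = "?", fenced = FALSE))
  if (flag == CIF_INAPPLICABLE) return(list(text = ".", fenced = FALSE))
  if (grepl("\n", value, fixed = TRUE)) {
    if (grepl("\n;", value, fixed = TRUE))
      stop("value contains a line starting with ';' and cannot be written ",
           "as a semicolon fence (mmCIF dialect limit)", call. = FALSE)
    return(list(text = paste0(";", value, "\n;"), fenced = TRUE))
  }
  if (!needsQuoting(value)) return(list(text = value, fenced = FALSE))
  if (quotable(value, "'")) return(list(text = paste0("'", value, "'"), fenced = FALSE))
  if (quotable(value, "\"")) return(list(text = paste0("\"", value, "\""), fenced = FALSE))
  list(text = paste0(";", value, "\n;"), fenced = TRUE)
}

writeCategoryKV <- function(cat, out) {
  width <- max(nchar(paste0("_", cat@name, ".", cat@items)))
  for (j in seq_along(cat@items)) {
    tag <- sprintf("%-*s", width, paste0("_", cat@name, ".", cat@items[[j]]))
    rv <- renderValue(cat@values[1L, j], cat@flags[1L, j])
    if (rv$fenced) out(paste0("_", cat@name, ".", cat@items[[j]]), paste0("\n", rv$text))
    else out(tag, paste0(" ", rv$text))
  }
}

writeCategoryLoop <- function(cat, out) {
  out("loop_", "")
  for (item in cat@items) out(paste0("_", cat@name, ".", item), "")
  for (i in seq_len(nrow(cat@values))) {
    parts <- character(0)
    for (j in seq_along(cat@items)) {
      rv <- renderValue(cat@values[i, j], cat@flags[i, j])
      if (rv$fenced) {
        if (length(parts)) { out(paste(parts, collapse = " "), ""); parts <- character(0) }
        out(rv$text, "")
      } else parts <- c(parts, rv$text)
    }
    if (length(parts)) out(paste(parts, collapse = " "), "")
  }
}

#' Serialize a CifDocument to mmCIF text
#'
#' The inverse of [parseCif()] up to formatting: `parseCif(writeCif(doc))` is
#' semantically equal to `doc` (see [cifEquals()]). Categories with one row
#' are written in key--value style, multi-row categories as `loop_`
#' constructs. Categories with zero rows are not representable in the format
#' and are omitted.
#'
#' @param doc a [CifDocument-class]
#' @param file optional path; when given the text is also written there
#' @return mmCIF text as a single string (invisibly when `file` is given)
#' @export
writeCif <- function(doc, file = NULL) {
  lines <- character(0)
  out <- function(a, b) lines[[length(lines) + 1L]] <<- paste0(a, b)
  writeBlockBody <- function(blk) {
    for (cat in blk@categories) {
      if (nrow(cat@values) == 0L) next
      out("#", "")
      if (nrow(cat@values) == 1L) writeCategoryKV(cat, out)
      else writeCategoryLoop(cat, out)
    }
  }
  for (blk in doc@blocks) {
    out("data_", blk@name)
    writeBlockBody(blk)
    for (fr in blk@frames) {
      out("save_", fr@name)
      writeBlockBody(fr)
      out("save_", "")
    }
    out("#", "")
  }
  text <- if (length(lines)) paste0(paste(lines, collapse = "\n"), "\n") else ""
  if (!is.null(file)) {
    writeLines(text, file, sep = "")
    return(invisible(text))
  }
  text
}
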