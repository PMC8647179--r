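## STAR-subset tokenizer and parser for PDBx/mmCIF. Line-oriented: comments,
## quoted strings and semicolon fences are resolved while scanning each line;
## the resulting token stream is folded into blocks/categories. Keywords
## (data_, loop_, save_) are case-insensitive; category and item names are
## folded to lowercase; values are preserved byte for byte.

cifSyntaxError <- function(line, msg) {
  stop(sprintf("mmCIF syntax error at line %d: %s", line, msg), call. = FALSE)
}

## Tokenize mmCIF text. Returns a data.frame-like list of parallel vectors:
## text, quoted (TRUE for quoted/fenced values), line.
cifTokenize <- function(source) {
  lines <- strsplit(gsub("\r\n?", "\n", source), "\n", fixed = TRUE)[[1]]
  texts <- character(0); quoted <- logical(0); linenos <- integer(0)
  push <- function(txt, q, ln) {
    texts[[length(texts) + 1L]] <<- txt
    quoted[[length(quoted) + 1L]] <<- q
    linenos[[length(linenos) + 1L]] <<- ln
  }
  i <- 1L
  nlines <- length(lines)
  while (i <= nlines) {
    line <- lines[[i]]
    if (startsWith(line, ";")) {
      ## semicolon fence: content runs to the next line whose first char is ';'
      content <- substring(line, 2L)
      start <- i
      i <- i + 1L
      closed <- FALSE
      while (i <= nlines) {
        if (startsWith(lines[[i]], ";")) { closed <- TRUE; break }
        content <- paste0(content, "\n", lines[[i]])
        i <- i + 1L
      }
      if (!closed) cifSyntaxError(start, "unterminated semicolon fence")
      push(content, TRUE, start)
      line <- substring(lines[[i]], 2L)  # tokens may follow the closing ';'
      ln <- i
      i <- i + 1L
      tokenizeLine(line, ln, push)
      next
    }
    tokenizeLine(line, i, push)
    i <- i + 1L
  }
  list(text = texts, quoted = quoted, line = linenos)
}

## Tokenize a single physical line (no fences), appending via push().
tokenizeLine <- function(line, lineno, push) {
  pos <- 1L
  n <- nchar(line)
  while (pos <= n) {
    ch <- substr(line, pos, pos)
    if (ch %in% c(" ", "\t")) { pos <- pos + 1L; next }
    if (ch == "#") break  # comment to end of line
    if (ch == "'" || ch == "\"") {
      ## closing quote must be followed by whitespace or end of line
      j <- pos + 1L
      close <- NA_integer_
      while (j <= n) {
        if (substr(line, j, j) == ch) {
          nxt <- if (j < n) substr(line, j + 1L, j + 1L) else " "
          if (nxt %in% c(" ", "\t")) { close <- j; break }
        }
        j <- j + 1L
      }
      if (is.na(close)) cifSyntaxError(lineno, sprintf("unterminated %s-quoted string", ch))
      push(substr(line, pos + 1L, close - 1L), TRUE, lineno)
      pos <- close + 1L
      next
    }
    j <- pos
    while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
    push(substr(line, pos, j - 1L), FALSE, lineno)
    pos <- j
  }
  invisible(NULL)
}

## Classify an unquoted token. Returns one of "data", "loop", "save",
## "unsupported", "tag", "value".
tokenKind <- function(text, quoted) {
  if (quoted) return("value")
  lower <- tolower(text)
  if (startsWith(lower, "data_")) return("data")
  if (lower == "loop_") return("loop")
  if (startsWith(lower, "save_")) return("save")
  if (lower %in% c("stop_", "global_")) return("unsupported")
  if (startsWith(text, "_")) return("tag")
  "value"
}

splitTag <- function(text, line) {
  body <- substring(text, 2L)
  dot <- regexpr(".", body, fixed = TRUE)
  if (dot < 1L || dot == nchar(body))
    cifSyntaxError(line, sprintf("item name '%s' lacks a category.item structure", text))
  c(tolower(substr(body, 1L, dot - 1L)), tolower(substring(body, dot + 1L)))
}

## Mutable category accumulator used during parsing.
newCatAcc <- function() new.env(parent = emptyenv())

accAddKeyValue <- function(acc, category, item, value, flag, line) {
  cur <- acc[[category]]
  if (is.null(cur)) {
    acc[[category]] <- list(items = item, cells = list(value), flags = flag,
                            loop = FALSE, order = length(ls(acc)) + 1L)
  } else {
    if (cur$loop)
      cifSyntaxError(line, sprintf("item _%s.%s assigned outside its loop", category, item))
    if (item %in% cur$items)
      cifSyntaxError(line, sprintf("duplicate item _%s.%s", category, item))
    cur$items <- c(cur$items, item)
    cur$cells <- c(cur$cells, list(value))
    cur$flags <- c(cur$flags, flag)
    acc[[category]] <- cur
  }
}

accAddLoop <- function(acc, category, items, values, flags, line) {
  if (!is.null(acc[[category]]))
    cifSyntaxError(line, sprintf("category '%s' defined more than once", category))
  acc[[category]] <- list(items = items, cells = values, flags = flags,
                          loop = TRUE, order = length(ls(acc)) + 1L)
}

accToCategories <- function(acc) {
  nms <- ls(acc)
  if (!length(nms)) return(list())
  ord <- order(vapply(nms, function(n) acc[[n]]$order, numeric(1)))
  out <- lapply(nms[ord], function(n) {
    entry <- acc[[n]]
    k <- length(entry$items)
    if (entry$loop) {
      nrows <- length(entry$cells) %/% k
      vals <- matrix(unlist(entry$cells, use.names = FALSE),
                     nrow = nrows, ncol = k, byrow = TRUE)
      flg <- matrix(entry$flags, nrow = nrows, ncol = k, byrow = TRUE)
    } else {
      vals <- matrix(unlist(entry$cells, use.names = FALSE), nrow = 1L, ncol = k)
      flg <- matrix(entry$flags, nrow = 1L, ncol = k)
    }
    vals[flg != CIF_TEXT] <- NA_character_
    new("CifCategory", name = n, items = entry$items, values = vals, flags = flg)
  })
  names(out) <- nms[ord]
  out
}

valueFlag <- function(text, quoted) {
  if (quoted) return(CIF_TEXT)
  if (text == "?") return(CIF_UNKNOWN)
  if (text == ".") return(CIF_INAPPLICABLE)
  CIF_TEXT
}

#' Parse mmCIF text into a CifDocument
#'
#' Supports the STAR subset used by the PDB archive: `data_` blocks,
#' key--value items, `loop_` constructs, single- and double-quoted values,
#' semicolon-fenced multiline values, `#` comments and the `?`/`.` sentinels.
#' Save frames (`save_`) are accepted and attached to their enclosing block;
#' they occur only in dictionary files.
#'
#' @param text mmCIF source text (single string), or `NULL` when `file` given
#' @param file path to a file to read instead of `text`
#' @return a [CifDocument-class]
#' @examples
#' doc <- parseCif("data_x\n_a.b 1\n")
#' cifBlockNames(doc)
#' @export
parseCif <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("give either text or file", call. = FALSE)
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  toks <- cifTokenize(text)
  n <- length(toks$text)
  blocks <- list()
  blockName <- NULL
  acc <- NULL            # category accumulator of the current block
  frameAcc <- NULL       # accumulator of the current save frame (or NULL)
  frameName <- NULL
  frames <- list()

  finishFrame <- function(line) {
    if (is.null(frameAcc)) return(invisible(NULL))
    fb <- cifBlock(frameName, accToCategories(frameAcc))
    frames[[length(frames) + 1L]] <<- fb
    frameAcc <<- NULL
    frameName <<- NULL
  }
  finishBlock <- function(line) {
    if (is.null(blockName)) return(invisible(NULL))
    if (!is.null(frameAcc)) cifSyntaxError(line, "unterminated save frame")
    blk <- cifBlock(blockName, accToCategories(acc), frames)
    if (blk@name %in% vapply(blocks, function(b) b@name, character(1)))
      cifSyntaxError(line, sprintf("duplicate data block '%s'", blk@name))
    blocks[[length(blocks) + 1L]] <<- blk
    blockName <<- NULL
    acc <<- NULL
    frames <<- list()
  }
  curAcc <- function() if (!is.null(frameAcc)) frameAcc else acc

  i <- 1L
  while (i <= n) {
    text_i <- toks$text[[i]]; quoted_i <- toks$quoted[[i]]; line_i <- toks$line[[i]]
    kind <- tokenKind(text_i, quoted_i)
    if (kind == "unsupported")
      cifSyntaxError(line_i, sprintf("unsupported STAR keyword '%s'", text_i))
    if (kind == "data") {
      finishBlock(line_i)
      blockName <- substring(text_i, 6L)
      if (!nzchar(blockName)) cifSyntaxError(line_i, "empty data block name")
      acc <- newCatAcc()
      i <- i + 1L
      next
    }
    if (is.null(blockName))
      cifSyntaxError(line_i, "content outside any data block")
    if (kind == "save") {
      nm <- substring(text_i, 6L)
      if (nzchar(nm)) {
        if (!is.null(frameAcc)) cifSyntaxError(line_i, "nested save frames are not supported")
        frameName <- nm
        frameAcc <- newCatAcc()
      } else {
        if (is.null(frameAcc)) cifSyntaxError(line_i, "save_ terminator outside a save frame")
        finishFrame(line_i)
      }
      i <- i + 1L
      next
    }
    if (kind == "tag") {
      parts <- splitTag(text_i, line_i)
      if (i + 1L > n)
        cifSyntaxError(line_i, sprintf("missing value for item %s", text_i))
      vk <- tokenKind(toks$text[[i + 1L]], toks$quoted[[i + 1L]])
      if (vk != "value")
        cifSyntaxError(line_i, sprintf("missing value for item %s", text_i))
      accAddKeyValue(curAcc(), parts[[1]], parts[[2]],
                     toks$text[[i + 1L]],
                     valueFlag(toks$text[[i + 1L]], toks$quoted[[i + 1L]]),
                     line_i)
      i <- i + 2L
      next
    }
    if (kind == "loop") {
      loopLine <- line_i
      i <- i + 1L
      items <- character(0); loopCat <- NULL
      while (i <= n && tokenKind(toks$text[[i]], toks$quoted[[i]]) == "tag") {
        parts <- splitTag(toks$text[[i]], toks$line[[i]])
        if (is.null(loopCat)) loopCat <- parts[[1]]
        else if (parts[[1]] != loopCat)
          cifSyntaxError(toks$line[[i]], "loop_ header spans multiple categories")
        if (parts[[2]] %in% items)
          cifSyntaxError(toks$line[[i]],
                         sprintf("duplicate item _%s.%s in loop", loopCat, parts[[2]]))
        items <- c(items, parts[[2]])
        i <- i + 1L
      }
      if (!length(items)) cifSyntaxError(loopLine, "loop_ without item names")
      vals <- list(); flags <- integer(0); lastLine <- loopLine
      while (i <= n && tokenKind(toks$text[[i]], toks$quoted[[i]]) == "value") {
        vals[[length(vals) + 1L]] <- toks$text[[i]]
        flags[[length(flags) + 1L]] <- valueFlag(toks$text[[i]], toks$quoted[[i]])
        lastLine <- toks$line[[i]]
        i <- i + 1L
      }
      if (!length(vals))
        cifSyntaxError(loopLine, sprintf("loop_ over '%s' has no values", loopCat))
      if (length(vals) %% length(items) != 0L)
        cifSyntaxError(lastLine,
                       sprintf("loop_ over '%s': %d values do not fill rows of %d columns",
                               loopCat, length(vals), length(items)))
      accAddLoop(curAcc(), loopCat, items, vals, flags, loopLine)
      next
    }
    ## bare value with no preceding tag
    cifSyntaxError(line_i, sprintf("unexpected value '%s' outside any item context", text_i))
  }
  finishBlock(if (n) toks$line[[n]] else 1L)
  cifDocument(blocks)
}
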