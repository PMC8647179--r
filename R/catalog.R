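## Archive catalog: entry summaries, archive-wide statistics and an
## in-memory search supporting boolean operators, wildcards and facet
## filters. The catalog is a plain data.frame with list columns so it can
## be persisted as JSON.

#' Summarize an entry for the archive catalog
#'
#' Composes the searchable catalog record: title, a short summary (built
#' from the entry title, entity descriptions, software and experimental
#' data types), author names, software, data types and feature flags
#' (multi-scale iff both atomic and sphere segments exist; multi-state iff
#' at least two states; ordered iff an ordered process exists).
#'
#' @param entry a curated [IhmEntry-class]
#' @param accession accession code for the catalog record
#' @return one-row catalog data.frame (list columns `data_types`,
#'   `software_names`, `authors`)
#' @export
entrySummary <- function(entry, accession) {
  dataTypes <- unique(entry@datasets$data_type)
  softwareNames <- unique(entry@software$name)
  descs <- vapply(entry@entities, function(e)
    if (is.null(e$description) || is.na(e$description)) "" else e$description,
    character(1))
  descs <- descs[nzchar(descs)]
  summary <- if (!is.na(entry@summary) && nzchar(entry@summary)) entry@summary
    else paste0(entry@title,
                if (length(descs)) paste0("; containing ", paste(descs, collapse = ", ")) else "",
                if (length(softwareNames)) paste0("; modeled with ",
                                                  paste(softwareNames, collapse = ", ")) else "",
                if (length(dataTypes)) paste0("; restraints from ",
                                              paste(dataTypes, collapse = ", ")) else "")
  multiScale <- any(entry@representations$mode == "atomic") &&
    any(entry@representations$mode == "sphere")
  data.frame(accession = accession, title = entry@title, summary = summary,
             data_types = I(list(dataTypes)),
             software_names = I(list(softwareNames)),
             authors = I(list(entry@authors)),
             multi_scale = multiScale,
             multi_state = nrow(entry@states) >= 2L,
             ordered = nrow(entry@ordered) >= 1L,
             stringsAsFactors = FALSE)
}

#' Combine catalog records
#' @param ... one-row catalog data.frames from [entrySummary()]
#' @return catalog data.frame; accessions must be unique
#' @export
catalogBind <- function(...) {
  cat <- do.call(rbind, list(...))
  if (anyDuplicated(cat$accession))
    stop("catalog accessions must be unique", call. = FALSE)
  rownames(cat) <- NULL
  cat
}

#' ArchiveStats: per-bucket archive counts
#'
#' Each entry contributes at most once to any bucket; an entry with k
#' distinct experimental data types contributes to k data-type buckets.
#' Buckets are ordered by descending count, then name.
#'
#' @slot n_entries catalog size
#' @slot counts_by_data_type,counts_by_software named integer vectors
#' @export
setClass("ArchiveStats",
  representation(n_entries = "integer", counts_by_data_type = "integer",
                 counts_by_software = "integer"))

setMethod("show", "ArchiveStats", function(object) {
  cat(sprintf("ArchiveStats over %d entries\n", object@n_entries))
  showCounts <- function(label, v) {
    cat(" ", label, "\n")
    for (nm in names(v)) cat(sprintf("    %-18s %d\n", nm, v[[nm]]))
  }
  showCounts("by experimental data type:", object@counts_by_data_type)
  showCounts("by modeling software:", object@counts_by_software)
})

bucketCounts <- function(lst) {
  vals <- unlist(lapply(lst, unique), use.names = FALSE)
  if (!length(vals)) return(stats::setNames(integer(0), character(0)))
  tab <- table(vals)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}

#' Archive statistics over a catalog
#'
#' @param catalog catalog data.frame (see [entrySummary()])
#' @return an [ArchiveStats-class]
#' @export
archiveStatistics <- function(catalog) {
  new("ArchiveStats", n_entries = nrow(catalog),
      counts_by_data_type = bucketCounts(catalog$data_types),
      counts_by_software = bucketCounts(catalog$software_names))
}

#' Persist or load a catalog as JSON
#' @param catalog catalog data.frame
#' @param path JSON file path
#' @return `readCatalog`: the catalog data.frame
#' @export
writeCatalog <- function(catalog, path) {
  jsonlite::write_json(catalog, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCatalog
#' @export
readCatalog <- function(path) {
  rows <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  do.call(rbind, lapply(rows, function(r) data.frame(
    accession = r$accession, title = r$title, summary = r$summary,
    data_types = I(list(unlist(r$data_types))),
    software_names = I(list(unlist(r$software_names))),
    authors = I(list(unlist(r$authors))),
    multi_scale = isTRUE(r$multi_scale), multi_state = isTRUE(r$multi_state),
    ordered = isTRUE(r$ordered), stringsAsFactors = FALSE)))
}

## ---- query language --------------------------------------------------------

tokenizeQuery <- function(query) {
  toks <- list()
  pos <- 1L
  n <- nchar(query)
  while (pos <= n) {
    ch <- substr(query, pos, pos)
    if (ch %in% c(" ", "\t")) { pos <- pos + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, pos = pos)
      pos <- pos + 1L
      next
    }
    m <- regmatches(substring(query, pos),
                    regexpr("^[A-Za-z0-9_*-]+", substring(query, pos)))
    if (!length(m))
      stop("query parse error at position ", pos, ": unexpected character '",
           ch, "'", call. = FALSE)
    type <- if (m %in% c("AND", "OR", "NOT")) m else "term"
    toks[[length(toks) + 1L]] <- list(type = type, text = m, pos = pos)
    pos <- pos + nchar(m)
  }
  toks
}

## grammar: or := and (OR and)* ; and := unary ((AND)? unary)* ;
## unary := NOT unary | '(' or ')' | term. Adjacent terms imply AND.
parseQuery <- function(query) {
  toks <- tokenizeQuery(query)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  take <- function() { t <- toks[[i]]; i <<- i + 1L; t }
  parseOr <- function() {
    node <- parseAnd()
    while (!is.null(peek()) && peek()$type == "OR") {
      take()
      node <- list(op = "or", a = node, b = parseAnd())
    }
    node
  }
  parseAnd <- function() {
    node <- parseUnary()
    repeat {
      t <- peek()
      if (is.null(t) || t$type %in% c("OR", ")")) break
      if (t$type == "AND") take()
      node <- list(op = "and", a = node, b = parseUnary())
    }
    node
  }
  parseUnary <- function() {
    t <- peek()
    if (is.null(t)) stop("query parse error: unexpected end of query", call. = FALSE)
    if (t$type == "NOT") { take(); return(list(op = "not", a = parseUnary())) }
    if (t$type == "(") {
      open <- take()
      node <- parseOr()
      cl <- peek()
      if (is.null(cl) || cl$type != ")")
        stop("query parse error at position ", open$pos,
             ": unbalanced parenthesis", call. = FALSE)
      take()
      return(node)
    }
    if (t$type == "term") { take(); return(list(op = "term", text = t$text)) }
    stop("query parse error at position ", t$pos, ": unexpected '", t$type, "'",
         call. = FALSE)
  }
  node <- parseOr()
  t <- peek()
  if (!is.null(t))
    stop("query parse error at position ", t$pos, ": unexpected '",
         if (t$type == "term") t$text else t$type, "'", call. = FALSE)
  node
}

catalogWords <- function(catalog) {
  lapply(seq_len(nrow(catalog)), function(i) {
    text <- paste(c(catalog$title[[i]], catalog$summary[[i]],
                    catalog$authors[[i]], catalog$software_names[[i]],
                    catalog$data_types[[i]]), collapse = " ")
    unique(tolower(strsplit(text, "[^A-Za-z0-9*-]+")[[1]]))
  })
}

termMatch <- function(words, term) {
  term <- tolower(term)
  if (endsWith(term, "*")) {
    prefix <- substr(term, 1L, nchar(term) - 1L)
    vapply(words, function(w) any(startsWith(w, prefix)), logical(1))
  } else {
    vapply(words, function(w) term %in% w, logical(1))
  }
}

evalQuery <- function(node, words) {
  switch(node$op,
    term = termMatch(words, node$text),
    and = evalQuery(node$a, words) & evalQuery(node$b, words),
    or = evalQuery(node$a, words) | evalQuery(node$b, words),
    not = !evalQuery(node$a, words))
}

#' Search the archive catalog
#'
#' Free-text query with boolean operators (`AND`, `OR`, `NOT`, uppercase),
#' parentheses and trailing-`*` wildcards; terms match words of the title,
#' summary, authors, software and data types case-insensitively (adjacent
#' terms imply `AND`). Facets refine the query results by exact attributes:
#' `data_type`, `software`, `author`, and the logical flags `multi_scale`,
#' `multi_state`, `ordered`. Results are accessions in ascending order.
#'
#' @param catalog catalog data.frame (see [entrySummary()])
#' @param query query string; empty string means "all entries"
#' @param facets named list of facet filters
#' @return character vector of matching accessions, sorted
#' @export
searchCatalog <- function(catalog, query = "", facets = list()) {
  if (!nzchar(trimws(query)) && !length(facets))
    stop("give a query or at least one facet", call. = FALSE)
  hits <- rep(TRUE, nrow(catalog))
  if (nzchar(trimws(query)))
    hits <- evalQuery(parseQuery(query), catalogWords(catalog))
  for (nm in names(facets)) {
    val <- facets[[nm]]
    hits <- hits & switch(nm,
      data_type = vapply(catalog$data_types, function(x) val %in% x, logical(1)),
      software = vapply(catalog$software_names, function(x) val %in% x, logical(1)),
      author = vapply(catalog$authors, function(x) val %in% x, logical(1)),
      multi_scale = catalog$multi_scale == isTRUE(val),
      multi_state = catalog$multi_state == isTRUE(val),
      ordered = catalog$ordered == isTRUE(val),
      stop("unknown facet '", nm, "'", call. = FALSE))
  }
  sort(catalog$accession[hits])
}
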