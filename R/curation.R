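## Curation procedures: attaching reference-sequence annotations, checking
## small-molecule nomenclature against a component dictionary, issuing
## accession codes and releasing entries.

#' Attach a reference-sequence annotation to an entry
#'
#' When the alignment identity reaches `minIdentity`, a sequence-reference
#' record (database, accession, aligned spans, identity) is appended to the
#' entry. Below the threshold a "sequence mismatch" curation finding is
#' raised and the entry is returned unchanged.
#'
#' @param entry an [IhmEntry-class]
#' @param entityRef id of the entity the reference describes
#' @param db reference database name (`"UniProt"` or `"INSDC"`)
#' @param accession reference accession
#' @param result an [AlignmentResult-class] from [alignToReference()]
#' @param minIdentity minimum percent identity to accept (default 95)
#' @return `list(entry=, findings=)`; `findings` is a data.frame (possibly
#'   empty) with columns `kind`, `entity`, `message`
#' @export
annotateReference <- function(entry, entityRef, db, accession, result,
                              minIdentity = 95) {
  if (is.null(entityById(entry, entityRef)))
    stop("no entity '", entityRef, "' in entry", call. = FALSE)
  db <- match.arg(db, c("UniProt", "INSDC"))
  noFindings <- data.frame(kind = character(0), entity = character(0),
                           message = character(0), stringsAsFactors = FALSE)
  if (result@identity_percent < minIdentity) {
    return(list(entry = entry, findings = data.frame(
      kind = "SEQUENCE_MISMATCH", entity = entityRef,
      message = sprintf("sequence mismatch: identity %.1f%% below threshold %g%% for %s %s",
                        result@identity_percent, minIdentity, db, accession),
      stringsAsFactors = FALSE)))
  }
  ref <- data.frame(entity_ref = entityRef, db = db, accession = accession,
                    model_begin = result@model_begin, model_end = result@model_end,
                    ref_begin = result@ref_begin, ref_end = result@ref_end,
                    identity_percent = result@identity_percent,
                    stringsAsFactors = FALSE)
  entry@seqReferences <- rbind(entry@seqReferences,
                               coerceTyped(ref, .entrySchemas$seqReferences,
                                           "seqReferences"))
  list(entry = entry, findings = noFindings)
}

#' Load chemical component definitions
#'
#' Reads a component file in the documented mmCIF dialect (category
#' `chem_comp` with items `id`, `name`, `formula`, `type`).
#' `miniChemCompDictionary()` loads the bundled synthetic mini component
#' dictionary (a ~20-entry stand-in for the full archive component
#' dictionary, sufficient for nomenclature checks in tests and examples).
#'
#' @param file path to a component definition file
#' @return data.frame with columns `comp_id`, `name`, `formula`, `comp_type`
#' @export
loadChemComp <- function(file) {
  doc <- parseCif(file = file)
  blk <- doc@blocks[[1L]]
  cat <- blk@categories[["chem_comp"]]
  if (is.null(cat)) stop("no chem_comp category in ", file, call. = FALSE)
  df <- categoryToDf(cat, c(comp_id = "id", name = "name", formula = "formula",
                            comp_type = "type"),
                     c(comp_id = "c", name = "c", formula = "c", comp_type = "c"),
                     blk@name)
  df
}

#' @rdname loadChemComp
#' @export
miniChemCompDictionary <- function() {
  loadChemComp(system.file("extdata", "mini_ccd.cif", package = "ihmforge",
                           mustWork = TRUE))
}

#' Check small-molecule nomenclature against a component dictionary
#'
#' Every non-polymer component in the entry must be present in the supplied
#' component dictionary, and the entry-level description must match the
#' dictionary name (case-insensitively). One finding is produced per
#' unknown component (`UNKNOWN_COMP`) and per name mismatch
#' (`NAME_MISMATCH`); matching components yield nothing.
#'
#' @param entry an [IhmEntry-class]
#' @param ccd component dictionary data.frame from [loadChemComp()]
#' @return data.frame with columns `kind`, `comp_id`, `message`
#' @export
checkChemComp <- function(entry, ccd = miniChemCompDictionary()) {
  out <- list()
  for (e in entry@entities) {
    if (e$kind == "polymer") next
    comp <- toupper(e$sequence[[1L]])
    hit <- ccd[toupper(ccd$comp_id) == comp, , drop = FALSE]
    if (!nrow(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        kind = "UNKNOWN_COMP", comp_id = comp,
        message = sprintf("component '%s' is not in the component dictionary", comp),
        stringsAsFactors = FALSE)
      next
    }
    desc <- e$description
    if (!is.null(desc) && !is.na(desc) && nzchar(desc) &&
        tolower(desc) != tolower(hit$name[[1L]]))
      out[[length(out) + 1L]] <- data.frame(
        kind = "NAME_MISMATCH", comp_id = comp,
        message = sprintf("component '%s' named '%s' but dictionary says '%s'",
                          comp, desc, hit$name[[1L]]),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(kind = character(0), comp_id = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## ---- accession registry ----------------------------------------------------

ACCESSION_PATTERN <- "^PDBDEV_[0-9]{8}$"

#' Accession-code registry
#'
#' Accession codes follow the sortable pattern `PDBDEV_` + zero-padded
#' 8-digit sequence number. The registry is a JSON file; issuance is
#' sequential, gap-free and idempotent per entry (re-issuing for the same
#' entry returns the existing code without consuming a number).
#'
#' @param path registry file path (created empty if missing)
#' @return `newAccessionRegistry`: the path, invisibly.
#' @export
newAccessionRegistry <- function(path) {
  if (!file.exists(path))
    writeRegistry(path, list(next_number = 1L, records = list()))
  invisible(path)
}

readRegistry <- function(path) {
  reg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  reg$next_number <- as.integer(reg$next_number)
  reg
}

writeRegistry <- function(path, reg) {
  tmp <- paste0(path, ".tmp")
  ok <- tryCatch({
    writeLines(jsonlite::toJSON(reg, auto_unbox = TRUE, pretty = TRUE), tmp)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    unlink(tmp)
    stop("registry write failed: ", conditionMessage(ok), call. = FALSE)
  }
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname newAccessionRegistry
#' @param entryRef entry identifier the code is issued for
#' @return `issueAccession`: `list(code=, entry_ref=, issued_at=)`
#' @export
issueAccession <- function(path, entryRef) {
  if (!file.exists(path)) stop("registry '", path, "' does not exist", call. = FALSE)
  reg <- readRegistry(path)
  for (rec in reg$records)
    if (identical(rec$entry_ref, entryRef)) return(rec)
  rec <- list(code = sprintf("PDBDEV_%08d", reg$next_number),
              entry_ref = entryRef,
              issued_at = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  reg$records[[length(reg$records) + 1L]] <- rec
  reg$next_number <- reg$next_number + 1L
  writeRegistry(path, reg)  # on failure nothing was consumed
  rec
}

#' @rdname newAccessionRegistry
#' @export
listAccessions <- function(path) {
  reg <- readRegistry(path)
  if (!length(reg$records))
    return(data.frame(code = character(0), entry_ref = character(0),
                      issued_at = character(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(reg$records, function(r)
    data.frame(code = r$code, entry_ref = r$entry_ref, issued_at = r$issued_at,
               stringsAsFactors = FALSE)))
}

#' Release a curated submission
#'
#' A curated (submitted) entry is released immediately, or kept on hold
#' until its publication appears. A held entry moves to released once the
#' publication flag is set. Release from any other workflow status is an
#' invalid transition.
#'
#' @param sub a [Submission-class] in status `SUBMIT` or `HOLD`
#' @param mode `"immediate"` or `"on_publication"`
#' @param publicationReleased has the associated publication appeared?
#' @return the updated [Submission-class]
#' @export
releaseEntry <- function(sub, mode = c("immediate", "on_publication"),
                         publicationReleased = FALSE) {
  mode <- match.arg(mode)
  if (submissionStatus(sub) == "HOLD") {
    if (publicationReleased)
      return(applyTransition(sub, "publication_release", "system",
                             "publication released"))
    return(sub)
  }
  if (mode == "immediate" || publicationReleased)
    return(applyTransition(sub, "release_immediate", "curator",
                           "released upon completion of data processing"))
  applyTransition(sub, "hold", "curator", "kept on hold for publication")
}

#' Read reference sequences from FASTA or plain text
#'
#' FASTA files (possibly multi-record) are read with Biostrings when
#' available; a plain text file containing a bare sequence is also accepted.
#'
#' @param file path to a FASTA or plain-text sequence file
#' @return named character vector of sequences
#' @export
referenceFromFasta <- function(file) {
  first <- readLines(file, n = 1L, warn = FALSE)
  if (length(first) && startsWith(first, ">")) {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      set <- Biostrings::readBStringSet(file)
      return(stats::setNames(as.character(set), names(set)))
    }
    ## minimal fallback; FASTA here is a line-oriented header/sequence list
    lines <- readLines(file, warn = FALSE)
    idx <- cumsum(startsWith(lines, ">"))
    headers <- sub("^>", "", lines[startsWith(lines, ">")])
    seqs <- vapply(split(lines[!startsWith(lines, ">")],
                         idx[!startsWith(lines, ">")]),
                   paste, character(1), collapse = "")
    return(stats::setNames(toupper(gsub("[^A-Za-z]", "", seqs)), headers))
  }
  seq <- paste(readLines(file, warn = FALSE), collapse = "")
  stats::setNames(toupper(gsub("[^A-Za-z]", "", seq)), basename(file))
}
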