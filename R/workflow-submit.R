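## Final submission: everything stored in the submission -- the processed
## model entry, metadata record versions, ingested restraints -- is merged
## into one entry, serialized as the aggregate mmCIF file and validated
## against the dictionary. Depositors with an already-complete compliant
## file skip the metadata/restraint steps entirely (the bypass path).

MANDATORY_METADATA_SECTIONS <- c("authors", "citations")

#' Build the aggregate entry from a submission
#'
#' Merges the parsed model entry with the latest version of each recorded
#' metadata section and the ingested restraints. Used by [submitSubmission()]
#' and exposed for inspection.
#'
#' @param sub a [Submission-class] with a processed model
#' @return an [IhmEntry-class]
#' @export
buildAggregateEntry <- function(sub) {
  if (is.null(sub@entry))
    stop("invalid state: model file has not been processed", call. = FALSE)
  entry <- sub@entry
  authors <- latestSection(sub, "authors")
  if (!is.null(authors))
    entry@authors <- as.character(authors$name[order(as.integer(authors$ordinal))])
  citations <- latestSection(sub, "citations")
  if (!is.null(citations)) {
    citTab <- citations[setdiff(names(citations), "authors")]
    entry@citations <- coerceTyped(citTab, .entrySchemas$citations, "citations")
    if ("authors" %in% names(citations)) {
      ca <- do.call(rbind, lapply(seq_len(nrow(citations)), function(i) {
        nm <- trimws(strsplit(citations$authors[[i]], ";", fixed = TRUE)[[1]])
        nm <- nm[nzchar(nm)]
        if (!length(nm)) return(NULL)
        data.frame(citation_ref = citations$id[[i]], ordinal = seq_along(nm),
                   name = nm, stringsAsFactors = FALSE)
      }))
      if (!is.null(ca))
        entry@citationAuthors <- coerceTyped(ca, .entrySchemas$citationAuthors,
                                             "citationAuthors")
    }
  }
  protocols <- latestSection(sub, "protocols")
  if (!is.null(protocols)) {
    names(protocols)[names(protocols) == "software_id"] <- "software_ref"
    names(protocols)[names(protocols) == "dataset_ids"] <- "dataset_refs"
    entry@protocolSteps <- coerceTyped(protocols, .entrySchemas$protocolSteps,
                                       "protocolSteps")
  }
  seqRefs <- latestSection(sub, "seq_refs")
  if (!is.null(seqRefs)) {
    names(seqRefs)[names(seqRefs) == "entity_id"] <- "entity_ref"
    names(seqRefs)[names(seqRefs) == "db_name"] <- "db"
    entry@seqReferences <- coerceTyped(seqRefs, .entrySchemas$seqReferences,
                                       "seqReferences")
  }
  datasets <- latestSection(sub, "dataset_refs")
  if (!is.null(datasets)) {
    ds <- coerceTyped(datasets, .entrySchemas$datasets, "datasets")
    keep <- entry@datasets[!entry@datasets$id %in% ds$id, , drop = FALSE]
    entry@datasets <- rbind(keep, ds)
    rownames(entry@datasets) <- NULL
  }
  if (nrow(sub@restraints))
    entry@crosslinks <- rbind(entry@crosslinks, sub@restraints)
  entry
}

#' Submit a deposition
#'
#' The final workflow step: all stored components are merged into one
#' entry, serialized as the aggregate mmCIF file (stored under the
#' `aggregate` role) and validated against the dictionary. A compliant
#' aggregate moves the submission to `SUBMIT`; a non-compliant one moves it
#' to `ERROR` with the compliance report attached. Preconditions (status
#' `ANNOT`, processed model file, mandatory metadata sections present
#' either as records or already inside the uploaded file) raise
#' invalid-state errors naming the missing piece.
#'
#' @param sub a [Submission-class] in status `ANNOT`
#' @param dict a [DictionaryModel-class] (default: the bundled dictionary)
#' @return the updated [Submission-class] with `@aggregate` and
#'   `@complianceReport` populated
#' @export
submitSubmission <- function(sub, dict = ihmDictionary()) {
  if (sub@status != "ANNOT")
    stop("invalid state: submission can be made only from status ANNOT (now ",
         sub@status, ")", call. = FALSE)
  if (is.null(sub@entry))
    stop("invalid state: model file has not been processed", call. = FALSE)
  for (section in MANDATORY_METADATA_SECTIONS) {
    inRecords <- !is.null(latestSection(sub, section))
    inEntry <- switch(section,
                      authors = length(sub@entry@authors) > 0L,
                      citations = nrow(sub@entry@citations) > 0L)
    if (!inRecords && !inEntry)
      stop("invalid state: mandatory metadata section '", section,
           "' is missing", call. = FALSE)
  }
  entry <- buildAggregateEntry(sub)
  doc <- entryToDocument(entry)
  st <- storeFile(sub, "aggregate", paste0(entry@id, ".cif"), writeCif(doc))
  sub <- st$sub
  sub@aggregate <- doc
  report <- validateDocument(doc, dict)
  sub@complianceReport <- report
  if (isCompliant(report))
    applyTransition(sub, "submit_ok", "depositor",
                    sprintf("aggregate '%s' compliant (%d warning(s))",
                            st$file$name,
                            sum(report@findings$severity == "warning")))
  else
    applyTransition(sub, "submit_fail", "system",
                    sprintf("aggregate not compliant: %d error(s)",
                            sum(report@findings$severity == "error")))
}
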