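## The data-harvesting workflow as an auditable state machine. A Submission
## carries stored files (content-addressed with SHA-256), versioned metadata
## records with point-in-time snapshots, ingested restraints, derived facts
## and an append-only status history. All operations are functional: they
## return the updated Submission.

WORKFLOW_STATUSES <- c("DRAFT", "PROC", "ERROR", "ANNOT", "SUBMIT", "HOLD", "REL")

## The complete transition table. Any (action, from) pair not listed is an
## invalid transition. PROC/ERROR/SUBMIT follow the archive's status
## vocabulary; DRAFT, ANNOT, HOLD and REL close the lifecycle.
.workflowTransitions <- data.frame(
  action = c("create", "process", "process", "process", "process_ok",
             "process_fail", "submit_ok", "submit_fail", "release_immediate",
             "hold", "publication_release"),
  from = c("NONE", "DRAFT", "ANNOT", "ERROR", "PROC",
           "PROC", "ANNOT", "ANNOT", "SUBMIT", "SUBMIT", "HOLD"),
  to = c("DRAFT", "PROC", "PROC", "PROC", "ANNOT",
         "ERROR", "SUBMIT", "ERROR", "REL", "HOLD", "REL"),
  stringsAsFactors = FALSE)

#' The workflow transition table
#'
#' @return data.frame with columns `action`, `from`, `to`; every allowed
#'   transition of the deposition state machine (the pseudo-status `NONE`
#'   precedes creation).
#' @export
workflowTransitions <- function() .workflowTransitions

#' Submission: one deposition moving through the harvesting workflow
#'
#' @slot entryId entry identifier
#' @slot depositorId opaque identifier of the depositing user
#' @slot status current workflow status (one of `r paste(WORKFLOW_STATUSES, collapse=", ")`)
#' @slot files list of stored-file records (`name`, `role`, `version`,
#'   `content_hash`, `size_bytes`, `stored_at`, `content`)
#' @slot records named list of versioned metadata records, keyed by record id
#' @slot statusHistory append-only data.frame of status events
#' @slot derivedFacts a [DerivedFacts-class] once the model file is processed
#' @slot entry the parsed [IhmEntry-class] from the model upload
#' @slot restraints ingested restraints (crosslink table layout)
#' @slot aggregate the aggregate [CifDocument-class] built at submission
#' @slot complianceReport the [ComplianceReport-class] for the aggregate
#' @slot releaseDate release date string, once released
#' @export
setClass("Submission",
  representation(entryId = "character", depositorId = "character",
                 status = "character", files = "list", records = "list",
                 statusHistory = "data.frame", derivedFacts = "ANY",
                 entry = "ANY", restraints = "data.frame", aggregate = "ANY",
                 complianceReport = "ANY", releaseDate = "character"))

setValidity("Submission", function(object) {
  msgs <- character(0)
  if (!object@status %in% WORKFLOW_STATUSES)
    msgs <- c(msgs, "unknown workflow status")
  h <- object@statusHistory
  if (nrow(h) && h$to[[nrow(h)]] != object@status)
    msgs <- c(msgs, "current status must equal the last event's target")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Submission", function(object) {
  cat(sprintf("Submission '%s' by '%s': status %s\n", object@entryId,
              object@depositorId, object@status))
  cat(sprintf("  %d file(s), %d metadata record(s), %d restraint(s), %d status event(s)\n",
              length(object@files), length(object@records),
              nrow(object@restraints), nrow(object@statusHistory)))
})

#' @rdname createSubmission
#' @param sub a [Submission-class]
#' @export
submissionStatus <- function(sub) sub@status

#' @rdname createSubmission
#' @export
statusHistory <- function(sub) sub@statusHistory

statusEvent <- function(from, to, actor, note) {
  data.frame(from = from, to = to, actor = actor, note = note,
             at = format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"),
             stringsAsFactors = FALSE)
}

applyTransition <- function(sub, action, actor, note = "") {
  tab <- .workflowTransitions
  row <- tab[tab$action == action & tab$from == sub@status, , drop = FALSE]
  if (!nrow(row))
    stop(sprintf("invalid transition: action '%s' is not allowed from status %s",
                 action, sub@status), call. = FALSE)
  sub@statusHistory <- rbind(sub@statusHistory,
                             statusEvent(sub@status, row$to[[1L]], actor, note))
  sub@status <- row$to[[1L]]
  sub
}

.submissionCounter <- new.env(parent = emptyenv())

#' Create a submission
#'
#' Authenticated users create an entry to start the harvesting workflow;
#' the new submission is in `DRAFT` with no files and a single creation
#' event in its history.
#'
#' @param depositorId non-empty opaque depositor identifier
#' @return a [Submission-class]
#' @export
createSubmission <- function(depositorId) {
  if (!nzchar(depositorId)) stop("depositor id must be non-empty", call. = FALSE)
  n <- (.submissionCounter$n <- if (is.null(.submissionCounter$n)) 1L
        else .submissionCounter$n + 1L)
  entryId <- sprintf("D_%06d%03d", as.integer(Sys.time()) %% 1000000L, n %% 1000L)
  new("Submission", entryId = entryId, depositorId = depositorId,
      status = "DRAFT", files = list(), records = list(),
      statusHistory = statusEvent("NONE", "DRAFT", "depositor", "entry created"),
      derivedFacts = NULL, entry = NULL,
      restraints = emptyTyped(.entrySchemas$crosslinks),
      aggregate = NULL, complianceReport = NULL, releaseDate = character(0))
}

#' Visibility rule for submissions
#'
#' Depositors see only their own submissions; curators and administrators
#' see all.
#'
#' @param sub a [Submission-class]
#' @param userId requesting user id
#' @param role `"depositor"`, `"curator"` or `"admin"`
#' @return logical
#' @export
submissionVisible <- function(sub, userId, role = c("depositor", "curator", "admin")) {
  role <- match.arg(role)
  role %in% c("curator", "admin") || identical(sub@depositorId, userId)
}

## ---- file storage ----------------------------------------------------------

FILE_ROLES <- c("model", "starting-model", "restraint-csv", "aggregate")

sha256hex <- function(raw) digest::digest(raw, algo = "sha256", serialize = FALSE)

#' Store a file in a submission
#'
#' Content is stored with its SHA-256 hash; re-uploading the same
#' `(name, role)` increments the version and keeps prior versions
#' retrievable. Stored files of released submissions are immutable.
#'
#' @param sub a [Submission-class] not in `REL`
#' @param role one of `model`, `starting-model`, `restraint-csv`, `aggregate`
#' @param name file name
#' @param content raw vector or character scalar
#' @return `list(sub=, file=)`; `file` is the stored-file record
#' @export
storeFile <- function(sub, role, name, content) {
  role <- match.arg(role, FILE_ROLES)
  if (sub@status == "REL")
    stop("invalid state: cannot store files in a released submission", call. = FALSE)
  if (is.character(content)) content <- charToRaw(paste(content, collapse = "\n"))
  versions <- vapply(sub@files, function(f)
    if (f$name == name && f$role == role) f$version else 0L, integer(1))
  rec <- list(name = name, role = role,
              version = (if (length(versions)) max(versions) else 0L) + 1L,
              content_hash = sha256hex(content),
              size_bytes = length(content),
              stored_at = format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"),
              content = content)
  sub@files[[length(sub@files) + 1L]] <- rec
  list(sub = sub, file = rec)
}

#' Retrieve a stored file, verifying integrity
#'
#' @param sub a [Submission-class]
#' @param name,role file identity
#' @param version version to read; default latest
#' @return the stored-file record; its hash is recomputed on read and an
#'   integrity error is raised on mismatch
#' @export
readStoredFile <- function(sub, name, role, version = NULL) {
  hits <- Filter(function(f) f$name == name && f$role == role, sub@files)
  if (!length(hits)) stop("no stored file '", name, "' with role ", role, call. = FALSE)
  if (is.null(version)) version <- max(vapply(hits, `[[`, integer(1), "version"))
  hit <- Filter(function(f) f$version == version, hits)
  if (!length(hit)) stop("no version ", version, " of '", name, "'", call. = FALSE)
  rec <- hit[[1L]]
  if (!identical(sha256hex(rec$content), rec$content_hash))
    stop("integrity check failed for '", name, "' v", version,
         ": stored hash does not match content", call. = FALSE)
  rec
}

## ---- model processing ------------------------------------------------------

#' Process an uploaded model file
#'
#' The automated agent step: the latest model-role file is parsed and facts
#' are derived from its coordinates. On success the submission moves
#' `DRAFT/ERROR -> PROC -> ANNOT` with `derivedFacts` (and the parsed entry)
#' populated; on failure it moves to `ERROR` with the error message recorded
#' in the event note, and a fixed file can be re-uploaded and re-processed.
#'
#' @param sub a [Submission-class] with a stored model file
#' @return the updated [Submission-class]
#' @export
processModelUpload <- function(sub) {
  models <- Filter(function(f) f$role == "model", sub@files)
  if (!length(models))
    stop("invalid state: no model file uploaded", call. = FALSE)
  latest <- models[[which.max(vapply(models, `[[`, integer(1), "version"))]]
  sub <- applyTransition(sub, "process", "system",
                         sprintf("processing '%s' v%d", latest$name, latest$version))
  res <- tryCatch({
    doc <- parseCif(rawToChar(latest$content))
    facts <- deriveEntryFacts(doc)
    entry <- entryFromDocument(doc)
    list(facts = facts, entry = entry)
  }, error = function(e) e)
  if (inherits(res, "error"))
    return(applyTransition(sub, "process_fail", "system", conditionMessage(res)))
  sub@derivedFacts <- res$facts
  sub@entry <- res$entry
  applyTransition(sub, "process_ok", "system",
                  sprintf("derived %d model(s), %d chain(s)",
                          res$facts@n_models, length(res$facts@asym_ids)))
}

## ---- versioned metadata records --------------------------------------------

.metadataSections <- c(authors = "audit_author", citations = "citation",
                       protocols = "protocol_step", seq_refs = "seq_reference",
                       dataset_refs = "dataset")

#' Record a metadata section as a new immutable version
#'
#' The payload (one or more records of the section's category) is validated
#' against the dictionary rules for that category -- mandatory items, data
#' types, controlled vocabularies and boundary conditions. An accepted
#' payload is stored as a new immutable [getSnapshot()]-able version of the
#' section's record; a rejected payload leaves the store unchanged and the
#' findings are returned.
#'
#' @param sub a [Submission-class] in status `ANNOT`
#' @param section one of `authors`, `citations`, `protocols`, `seq_refs`,
#'   `dataset_refs`
#' @param payload data.frame (or single-record named list) of the section's
#'   category items; a `citations` payload may carry an extra `authors`
#'   field (semicolon-separated names)
#' @param dict a [DictionaryModel-class] (default: the bundled dictionary)
#' @return `list(sub=, record=, findings=)`; `record` is `NULL` on rejection
#' @export
recordMetadata <- function(sub, section, payload, dict = ihmDictionary()) {
  if (!section %in% names(.metadataSections))
    stop("unknown metadata section '", section, "'; one of: ",
         paste(names(.metadataSections), collapse = ", "), call. = FALSE)
  if (sub@status != "ANNOT")
    stop("invalid state: metadata can be recorded only in status ANNOT (now ",
         sub@status, ")", call. = FALSE)
  if (!is.data.frame(payload))
    payload <- as.data.frame(payload, stringsAsFactors = FALSE)
  category <- .metadataSections[[section]]
  toValidate <- payload[setdiff(names(payload), "authors")]
  if (section != "citations") toValidate <- payload
  findings <- validateCategoryPayload(toValidate, category, dict,
                                      blockName = sub@entryId)
  if (any(findings$severity == "error"))
    return(list(sub = sub, record = NULL, findings = findings))
  recordId <- paste0(sub@entryId, ":", section)
  rec <- sub@records[[recordId]]
  if (is.null(rec)) rec <- list(record_id = recordId, section = section,
                                versions = list())
  rec$versions[[length(rec$versions) + 1L]] <- list(
    payload = payload, created_at = format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"))
  sub@records[[recordId]] <- rec
  list(sub = sub,
       record = list(record_id = recordId, version = length(rec$versions)),
       findings = findings)
}

#' Point-in-time snapshot of a metadata record
#'
#' Versions number 1..latest with no gaps; each snapshot is immutable, so
#' the history of changes is reconstructable by iterating versions.
#'
#' @param sub a [Submission-class]
#' @param recordId record identifier (`"<entryId>:<section>"`)
#' @param version version number; default latest
#' @return the stored payload (data.frame)
#' @export
getSnapshot <- function(sub, recordId, version = NULL) {
  rec <- sub@records[[recordId]]
  if (is.null(rec)) stop("not found: record '", recordId, "'", call. = FALSE)
  if (is.null(version)) version <- length(rec$versions)
  if (version < 1L || version > length(rec$versions))
    stop("not found: version ", version, " of record '", recordId, "'",
         call. = FALSE)
  rec$versions[[version]]$payload
}

latestSection <- function(sub, section) {
  rec <- sub@records[[paste0(sub@entryId, ":", section)]]
  if (is.null(rec)) NULL else rec$versions[[length(rec$versions)]]$payload
}
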