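## The integrative-structure domain model. An IhmEntry holds everything a
## deposition carries: molecular entities and their placed chains (asym
## units), the modeled assembly, a multi-scale representation (atomic
## segments and coarse-grained sphere segments), model coordinates, state and
## ordering structure, ensembles, external datasets, starting models,
## cross-link restraints, fit metrics, protocols, software, citations and
## reference-sequence annotations.
##
## Tabular collections are stored as typed data.frames mapping 1:1 onto the
## documented mmCIF category layout (see entry-io.R); entities are a list
## because each carries a variable-length component sequence.

## Column schema per tabular slot: c = character, i = integer, n = numeric,
## l = logical. Used to build empty prototypes and to coerce on construction.
.entrySchemas <- list(
  asyms            = c(id = "c", entity_ref = "c"),
  assemblies       = c(id = "c", asym_ref = "c", seq_begin = "i", seq_end = "i"),
  representations  = c(id = "c", asym_ref = "c", seq_begin = "i", seq_end = "i",
                       mode = "c", granularity = "c", is_rigid = "l",
                       starting_model_ref = "c"),
  models           = c(id = "c", assembly_ref = "c", representation_ref = "c",
                       protocol_ref = "c"),
  atoms            = c(model_ref = "c", asym_ref = "c", seq_id = "i",
                       comp_id = "c", atom_name = "c", element = "c",
                       x = "n", y = "n", z = "n"),
  spheres          = c(model_ref = "c", asym_ref = "c", seq_begin = "i",
                       seq_end = "i", x = "n", y = "n", z = "n",
                       radius = "n", rmsf = "n"),
  modelGroups      = c(id = "c", name = "c"),
  modelGroupLinks  = c(group_id = "c", model_id = "c"),
  states           = c(id = "c", name = "c", population_fraction = "n"),
  stateLinks       = c(state_id = "c", group_id = "c"),
  stateGroups      = c(id = "c"),
  stateGroupLinks  = c(state_group_id = "c", state_id = "c"),
  ordered          = c(id = "c", ordered_by = "c"),
  orderedSteps     = c(process_id = "c", step_index = "i",
                       from_group_id = "c", to_group_id = "c"),
  ensembles        = c(id = "c", group_ref = "c", num_models_total = "i",
                       num_models_deposited = "i", clustering_method = "c"),
  datasets         = c(id = "c", data_type = "c", db_name = "c",
                       accession = "c", doi = "c", file_path = "c"),
  startingModels   = c(id = "c", asym_ref = "c", seq_begin = "i",
                       seq_end = "i", source_type = "c", dataset_ref = "c"),
  crosslinks       = c(id = "c", group_id = "c",
                       entity_ref_1 = "c", asym_ref_1 = "c", seq_id_1 = "i",
                       atom_name_1 = "c",
                       entity_ref_2 = "c", asym_ref_2 = "c", seq_id_2 = "i",
                       atom_name_2 = "c",
                       linker = "c", threshold = "n", restraint_form = "c",
                       granularity = "c", conditionality = "c",
                       dataset_ref = "c"),
  fitMetrics       = c(restraint_kind = "c", dataset_ref = "c",
                       model_ref = "c", metric_name = "c", metric_value = "n"),
  protocolSteps    = c(protocol_id = "c", step_index = "i", method_name = "c",
                       num_models_begin = "i", num_models_end = "i",
                       multi_scale = "l", multi_state = "l", ordered = "l",
                       software_ref = "c", dataset_refs = "c"),
  software         = c(id = "c", name = "c", version = "c",
                       classification = "c", location = "c"),
  citations        = c(id = "c", title = "c", journal = "c", doi = "c",
                       pmid = "c"),
  citationAuthors  = c(citation_ref = "c", ordinal = "i", name = "c"),
  seqReferences    = c(entity_ref = "c", db = "c", accession = "c",
                       model_begin = "i", model_end = "i",
                       ref_begin = "i", ref_end = "i", identity_percent = "n")
)

emptyTyped <- function(schema) {
  cols <- lapply(schema, function(t)
    switch(t, c = character(0), i = integer(0), n = numeric(0), l = logical(0)))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

coerceTyped <- function(df, schema, what) {
  missing <- setdiff(names(schema), names(df))
  for (m in missing) df[[m]] <- rep(switch(schema[[m]],
    c = NA_character_, i = NA_integer_, n = NA_real_, l = NA), nrow(df))
  df <- df[names(schema)]
  for (nm in names(schema)) {
    df[[nm]] <- switch(schema[[nm]],
      c = as.character(df[[nm]]),
      i = as.integer(df[[nm]]),
      n = as.numeric(df[[nm]]),
      l = as.logical(df[[nm]]))
  }
  rownames(df) <- NULL
  df
}

#' IhmEntry: one integrative-structure deposition
#'
#' The domain object graph for a single archive entry: entities, asym units,
#' assemblies, multi-scale representations, models (atoms and coarse-grained
#' spheres), model groups, states, ordered processes, ensembles, external
#' datasets, starting models, cross-link restraints, depositor-provided fit
#' metrics, modeling protocols, software, citations and reference-sequence
#' annotations. Use [ihmEntry()] to construct, [entryToDocument()] /
#' [entryFromDocument()] to serialize, and [validateReferentialIntegrity()]
#' to check referential closure.
#'
#' @slot id entry identifier
#' @slot title entry title
#' @slot summary optional free-text summary (`NA` when absent)
#' @slot authors character vector of deposition author names
#' @slot entities list of entity records: `list(id, kind, polymer_type,
#'   sequence, description)` where `sequence` is a character vector of
#'   3-letter component codes (length 1 for non-polymers)
#' @slot asyms,assemblies,representations,models,atoms,spheres data.frames
#'   (see the package vignette for the column layout)
#' @slot modelGroups,modelGroupLinks,states,stateLinks,stateGroups,stateGroupLinks
#'   data.frames describing the multi-state organisation
#' @slot ordered,orderedSteps data.frames describing ordered processes
#' @slot ensembles,datasets,startingModels,crosslinks,fitMetrics,protocolSteps
#'   data.frames
#' @slot software,citations,citationAuthors,seqReferences data.frames
#' @slot extras list of [CifCategory-class] objects preserved opaquely from
#'   categories this model does not interpret (lossless passthrough)
#' @export
setClass("IhmEntry",
  representation(
    id = "character", title = "character", summary = "character",
    authors = "character", entities = "list",
    asyms = "data.frame", assemblies = "data.frame",
    representations = "data.frame", models = "data.frame",
    atoms = "data.frame", spheres = "data.frame",
    modelGroups = "data.frame", modelGroupLinks = "data.frame",
    states = "data.frame", stateLinks = "data.frame",
    stateGroups = "data.frame", stateGroupLinks = "data.frame",
    ordered = "data.frame", orderedSteps = "data.frame",
    ensembles = "data.frame", datasets = "data.frame",
    startingModels = "data.frame", crosslinks = "data.frame",
    fitMetrics = "data.frame", protocolSteps = "data.frame",
    software = "data.frame", citations = "data.frame",
    citationAuthors = "data.frame", seqReferences = "data.frame",
    extras = "list"))

setValidity("IhmEntry", function(object) {
  msgs <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msgs <- c(msgs, "entry id must be a single non-empty string")
  for (nm in names(.entrySchemas)) {
    df <- slot(object, nm)
    if (!identical(names(df), names(.entrySchemas[[nm]])))
      msgs <- c(msgs, sprintf("slot '%s' must have columns %s", nm,
                              paste(names(.entrySchemas[[nm]]), collapse = ", ")))
  }
  for (e in object@entities) {
    need <- c("id", "kind", "polymer_type", "sequence", "description")
    if (!all(need %in% names(e))) {
      msgs <- c(msgs, "each entity needs id, kind, polymer_type, sequence, description")
      next
    }
    if (!e$kind %in% c("polymer", "nonpolymer", "water"))
      msgs <- c(msgs, sprintf("entity '%s': kind must be polymer/nonpolymer/water", e$id))
    if (e$kind == "polymer" && length(e$sequence) < 1L)
      msgs <- c(msgs, sprintf("entity '%s': polymer needs a sequence", e$id))
    if (e$kind != "polymer" && length(e$sequence) != 1L)
      msgs <- c(msgs, sprintf("entity '%s': non-polymer needs exactly one component", e$id))
  }
  ids <- vapply(object@entities, function(e) e$id, character(1))
  if (anyDuplicated(ids)) msgs <- c(msgs, "entity ids must be unique")
  if (anyDuplicated(object@asyms$id)) msgs <- c(msgs, "asym ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct an IhmEntry
#'
#' All collections default to empty; tabular arguments are coerced to the
#' documented column schema (missing optional columns become `NA`).
#'
#' @param id entry identifier (non-empty)
#' @param title entry title
#' @param summary optional summary text
#' @param authors character vector of author names
#' @param entities list of entity records (see [IhmEntry-class])
#' @param ... tabular slots by name (`asyms`, `atoms`, `crosslinks`, ...)
#' @param extras list of [CifCategory-class] passthrough categories
#' @return an [IhmEntry-class]
#' @export
ihmEntry <- function(id, title = "", summary = NA_character_,
                     authors = character(0), entities = list(), ...,
                     extras = list()) {
  dots <- list(...)
  bad <- setdiff(names(dots), names(.entrySchemas))
  if (length(bad))
    stop("unknown IhmEntry slots: ", paste(bad, collapse = ", "), call. = FALSE)
  args <- list(Class = "IhmEntry", id = id, title = title, summary = summary,
               authors = authors, entities = entities, extras = extras)
  for (nm in names(.entrySchemas)) {
    df <- if (nm %in% names(dots)) dots[[nm]] else emptyTyped(.entrySchemas[[nm]])
    args[[nm]] <- coerceTyped(as.data.frame(df, stringsAsFactors = FALSE),
                              .entrySchemas[[nm]], nm)
  }
  do.call(new, args)
}

#' Accessors for IhmEntry collections
#'
#' @param entry an [IhmEntry-class]
#' @return `entryId`/`entryTitle`: string; `entities`: list of entity
#'   records; `entryTable`: the named tabular slot as a data.frame.
#' @export
entryId <- function(entry) entry@id

#' @rdname entryId
#' @export
entryTitle <- function(entry) entry@title

#' @rdname entryId
#' @export
entities <- function(entry) entry@entities

#' @rdname entryId
#' @param name tabular slot name, e.g. `"atoms"`, `"crosslinks"`
#' @export
entryTable <- function(entry, name) {
  if (!name %in% names(.entrySchemas))
    stop("no tabular slot '", name, "'; one of: ",
         paste(names(.entrySchemas), collapse = ", "), call. = FALSE)
  slot(entry, name)
}

entityById <- function(entry, id) {
  for (e in entry@entities) if (e$id == id) return(e)
  NULL
}

setMethod("show", "IhmEntry", function(object) {
  cat(sprintf("IhmEntry '%s'%s\n", object@id,
              if (nzchar(object@title)) paste0(": ", object@title) else ""))
  cat(sprintf("  %d entities, %d asym units, %d models (%d atoms, %d spheres)\n",
              length(object@entities), nrow(object@asyms), nrow(object@models),
              nrow(object@atoms), nrow(object@spheres)))
  cat(sprintf("  %d states, %d model groups, %d ordered processes, %d ensembles\n",
              nrow(object@states), nrow(object@modelGroups),
              nrow(object@ordered), nrow(object@ensembles)))
  cat(sprintf("  %d cross-links, %d datasets, %d protocol steps, %d extras\n",
              nrow(object@crosslinks), nrow(object@datasets),
              nrow(object@protocolSteps), length(object@extras)))
})

#' Compare two entries for semantic equality
#'
#' Scalar slots, entity lists, tabular slots (ignoring row names, with a
#' small numeric tolerance) and passthrough extras are compared.
#'
#' @param a,b [IhmEntry-class] objects
#' @param tolerance numeric tolerance for coordinate-like columns
#' @return `TRUE`, or `FALSE` with attribute `"difference"`
#' @export
entriesEqual <- function(a, b, tolerance = 1e-6) {
  fail <- function(msg) structure(FALSE, difference = msg)
  if (!identical(a@id, b@id)) return(fail("entry id differs"))
  if (!identical(a@title, b@title)) return(fail("title differs"))
  if (!identical(is.na(a@summary), is.na(b@summary)) ||
      !isTRUE(all(a@summary == b@summary) || all(is.na(a@summary))))
    return(fail("summary differs"))
  if (!identical(a@authors, b@authors)) return(fail("authors differ"))
  if (length(a@entities) != length(b@entities)) return(fail("entity count differs"))
  for (i in seq_along(a@entities)) {
    ea <- a@entities[[i]][c("id", "kind", "polymer_type", "sequence", "description")]
    eb <- b@entities[[i]][c("id", "kind", "polymer_type", "sequence", "description")]
    if (!isTRUE(all.equal(ea, eb)))
      return(fail(sprintf("entity %d differs", i)))
  }
  for (nm in names(.entrySchemas)) {
    da <- slot(a, nm); db <- slot(b, nm)
    rownames(da) <- NULL; rownames(db) <- NULL
    cmp <- all.equal(da, db, tolerance = tolerance, check.attributes = FALSE)
    if (!isTRUE(cmp))
      return(fail(sprintf("slot '%s': %s", nm, paste(cmp, collapse = "; "))))
  }
  if (length(a@extras) != length(b@extras)) return(fail("extras count differs"))
  for (i in seq_along(a@extras)) {
    d <- categoryDiff("<extras>", a@extras[[i]], b@extras[[i]])
    if (!is.null(d)) return(fail(d))
  }
  TRUE
}
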