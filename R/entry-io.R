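## Mapping between IhmEntry and its documented mmCIF category layout.
## One category per tabular slot, plus `entry`, `audit_author`, `entity` and
## `entity_seq`. The layout is this package's own (documented in the
## vignette); unknown categories round-trip opaquely through @extras.
## Serialization always uses exactly one data block named after the entry id.

## category item name per slot column, in serialization order
.categoryLayout <- list(
  list(category = "citation", slot = "citations",
       items = c(id = "id", title = "title", journal = "journal",
                 doi = "doi", pmid = "pmid")),
  list(category = "citation_author", slot = "citationAuthors",
       items = c(citation_ref = "citation_id", ordinal = "ordinal", name = "name")),
  list(category = "software", slot = "software",
       items = c(id = "id", name = "name", version = "version",
                 classification = "classification", location = "location")),
  list(category = "struct_asym", slot = "asyms",
       items = c(id = "id", entity_ref = "entity_id")),
  list(category = "assembly", slot = "assemblies",
       items = c(id = "id", asym_ref = "asym_id",
                 seq_begin = "seq_begin", seq_end = "seq_end")),
  list(category = "representation_segment", slot = "representations",
       items = c(id = "representation_id", asym_ref = "asym_id",
                 seq_begin = "seq_begin", seq_end = "seq_end", mode = "mode",
                 granularity = "granularity", is_rigid = "is_rigid",
                 starting_model_ref = "starting_model_id")),
  list(category = "starting_model", slot = "startingModels",
       items = c(id = "id", asym_ref = "asym_id", seq_begin = "seq_begin",
                 seq_end = "seq_end", source_type = "source_type",
                 dataset_ref = "dataset_id")),
  list(category = "dataset", slot = "datasets",
       items = c(id = "id", data_type = "data_type", db_name = "db_name",
                 accession = "accession", doi = "doi", file_path = "file_path")),
  list(category = "model", slot = "models",
       items = c(id = "id", assembly_ref = "assembly_id",
                 representation_ref = "representation_id",
                 protocol_ref = "protocol_id")),
  list(category = "atom_site", slot = "atoms",
       items = c(model_ref = "model_id", asym_ref = "asym_id",
                 seq_id = "seq_id", comp_id = "comp_id", atom_name = "atom_id",
                 element = "type_symbol", x = "cartn_x", y = "cartn_y",
                 z = "cartn_z")),
  list(category = "sphere_site", slot = "spheres",
       items = c(model_ref = "model_id", asym_ref = "asym_id",
                 seq_begin = "seq_begin", seq_end = "seq_end",
                 x = "cartn_x", y = "cartn_y", z = "cartn_z",
                 radius = "radius", rmsf = "rmsf")),
  list(category = "model_group", slot = "modelGroups",
       items = c(id = "id", name = "name")),
  list(category = "model_group_link", slot = "modelGroupLinks",
       items = c(group_id = "group_id", model_id = "model_id")),
  list(category = "state", slot = "states",
       items = c(id = "id", name = "name",
                 population_fraction = "population_fraction")),
  list(category = "state_link", slot = "stateLinks",
       items = c(state_id = "state_id", group_id = "group_id")),
  list(category = "state_group", slot = "stateGroups", items = c(id = "id")),
  list(category = "state_group_link", slot = "stateGroupLinks",
       items = c(state_group_id = "state_group_id", state_id = "state_id")),
  list(category = "ordered_process", slot = "ordered",
       items = c(id = "id", ordered_by = "ordered_by")),
  list(category = "ordered_step", slot = "orderedSteps",
       items = c(process_id = "process_id", step_index = "step_index",
                 from_group_id = "from_group_id", to_group_id = "to_group_id")),
  list(category = "ensemble", slot = "ensembles",
       items = c(id = "id", group_ref = "group_id",
                 num_models_total = "num_models_total",
                 num_models_deposited = "num_models_deposited",
                 clustering_method = "clustering_method")),
  list(category = "crosslink_restraint", slot = "crosslinks",
       items = c(id = "id", group_id = "group_id",
                 entity_ref_1 = "entity_id_1", asym_ref_1 = "asym_id_1",
                 seq_id_1 = "seq_id_1", atom_name_1 = "atom_id_1",
                 entity_ref_2 = "entity_id_2", asym_ref_2 = "asym_id_2",
                 seq_id_2 = "seq_id_2", atom_name_2 = "atom_id_2",
                 linker = "linker", threshold = "threshold_a",
                 restraint_form = "restraint_form", granularity = "granularity",
                 conditionality = "conditionality", dataset_ref = "dataset_id")),
  list(category = "fit_metric", slot = "fitMetrics",
       items = c(restraint_kind = "restraint_kind", dataset_ref = "dataset_id",
                 model_ref = "model_id", metric_name = "metric_name",
                 metric_value = "metric_value")),
  list(category = "protocol_step", slot = "protocolSteps",
       items = c(protocol_id = "protocol_id", step_index = "step_index",
                 method_name = "method_name",
                 num_models_begin = "num_models_begin",
                 num_models_end = "num_models_end", multi_scale = "multi_scale",
                 multi_state = "multi_state", ordered = "ordered",
                 software_ref = "software_id", dataset_refs = "dataset_ids")),
  list(category = "seq_reference", slot = "seqReferences",
       items = c(entity_ref = "entity_id", db = "db_name",
                 accession = "accession", model_begin = "model_begin",
                 model_end = "model_end", ref_begin = "ref_begin",
                 ref_end = "ref_end", identity_percent = "identity_percent"))
)

.knownCategories <- c("entry", "audit_author", "entity", "entity_seq",
                      vapply(.categoryLayout, `[[`, character(1), "category"))

## trimmed fixed-point rendering: stable through a parse/format cycle for
## values already at <= 6 decimals
fmtNum <- function(x) {
  out <- sprintf("%.6f", x)
  out <- sub("0+$", "", out)
  sub("\\.$", "", out)
}

renderColumn <- function(x, type) {
  switch(type,
    c = as.character(x),
    i = as.character(x),
    n = ifelse(is.na(x), NA_character_, fmtNum(x)),
    l = ifelse(is.na(x), NA_character_, ifelse(x, "yes", "no")))
}

dfToCategory <- function(df, category, items, schema) {
  rows <- list()
  flags <- matrix(CIF_TEXT, nrow = nrow(df), ncol = length(items))
  for (j in seq_along(items)) {
    col <- names(items)[[j]]
    vals <- renderColumn(df[[col]], schema[[col]])
    flags[is.na(vals), j] <- CIF_INAPPLICABLE
    rows[[items[[j]]]] <- vals
  }
  cifCategory(category, rows, flags)
}

parseCell <- function(txt, type, block, category, item, row) {
  if (is.na(txt)) return(switch(type, c = NA_character_, i = NA_integer_,
                                n = NA_real_, l = NA))
  bad <- function(what) stop(sprintf(
    "malformed %s cell in block '%s', category '%s', item '%s', row %d: '%s'",
    what, block, category, item, row, txt), call. = FALSE)
  switch(type,
    c = txt,
    i = { if (!grepl("^[+-]?[0-9]+$", txt)) bad("integer"); as.integer(txt) },
    n = { v <- suppressWarnings(as.numeric(txt)); if (is.na(v)) bad("numeric"); v },
    l = { if (!tolower(txt) %in% c("yes", "no")) bad("yes/no flag")
          tolower(txt) == "yes" })
}

categoryToDf <- function(cat, items, schema, block) {
  df <- emptyTyped(schema[names(items)])
  tab <- categoryTable(cat)
  n <- categoryRowCount(cat)
  out <- list()
  for (j in seq_along(items)) {
    col <- names(items)[[j]]; item <- items[[j]]
    raw <- if (item %in% itemNames(cat)) tab[[item]] else rep(NA_character_, n)
    type <- schema[[col]]
    out[[col]] <- vapply(seq_len(n), function(i)
      parseCell(raw[[i]], type, block, cat@name, item, i),
      switch(type, c = character(1), i = integer(1), n = numeric(1), l = logical(1)))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Serialize an IhmEntry to a CifDocument
#'
#' Produces a single data block named after the entry id, with one category
#' per populated collection in a fixed, documented order; absent optional
#' values are emitted as the inapplicable sentinel (`.`). Opaque passthrough
#' categories (`@extras`) are re-emitted last. Serialization is
#' deterministic: the same entry always yields byte-identical text via
#' [writeCif()].
#'
#' @param entry an [IhmEntry-class]; referential integrity must hold
#' @return a [CifDocument-class]
#' @export
entryToDocument <- function(entry) {
  findings <- validateReferentialIntegrity(entry)
  if (nrow(findings))
    stop("entry has unresolved references:\n",
         paste0("  - ", findings$message, collapse = "\n"), call. = FALSE)
  cats <- list()
  add <- function(cat) if (categoryRowCount(cat) > 0L) cats[[length(cats) + 1L]] <<- cat

  add(cifCategory("entry", list(id = entry@id, title = entry@title,
                                summary = entry@summary)))
  if (length(entry@authors))
    add(cifCategory("audit_author",
                    list(ordinal = as.character(seq_along(entry@authors)),
                         name = entry@authors)))
  if (length(entry@entities)) {
    add(cifCategory("entity", list(
      id = vapply(entry@entities, `[[`, character(1), "id"),
      type = vapply(entry@entities, `[[`, character(1), "kind"),
      polymer_type = vapply(entry@entities, function(e)
        if (is.null(e$polymer_type)) NA_character_ else e$polymer_type, character(1)),
      description = vapply(entry@entities, function(e)
        if (is.null(e$description)) NA_character_ else e$description, character(1)))))
    seqs <- do.call(rbind, lapply(entry@entities, function(e)
      data.frame(entity_id = e$id, num = as.character(seq_along(e$sequence)),
                 comp_id = e$sequence, stringsAsFactors = FALSE)))
    add(cifCategory("entity_seq", seqs))
  }
  for (lay in .categoryLayout) {
    df <- slot(entry, lay$slot)
    if (nrow(df))
      add(dfToCategory(df, lay$category, lay$items, .entrySchemas[[lay$slot]]))
  }
  for (ex in entry@extras) add(ex)
  cifDocument(list(cifBlock(entry@id, cats)))
}

#' Read an IhmEntry from a CifDocument
#'
#' The inverse of [entryToDocument()] on its image. A deposition document
#' must contain exactly one data block; categories this model does not
#' interpret are retained opaquely in `@extras` and re-emitted on write.
#'
#' @param doc a parsed [CifDocument-class]
#' @return an [IhmEntry-class]
#' @export
entryFromDocument <- function(doc) {
  if (length(doc@blocks) != 1L)
    stop("a deposition document must contain exactly one data block (found ",
         length(doc@blocks), ")", call. = FALSE)
  blk <- doc@blocks[[1L]]
  cats <- blk@categories
  if (!"entity" %in% names(cats))
    stop("missing required category 'entity'", call. = FALSE)
  if (!any(c("atom_site", "sphere_site") %in% names(cats)))
    stop("no models found: document lacks coordinate categories ",
         "('atom_site'/'sphere_site')", call. = FALSE)

  getdf <- function(category, items, schemaCols) {
    if (!category %in% names(cats)) return(emptyTyped(schemaCols))
    categoryToDf(cats[[category]], items, schemaCols, blk@name)
  }
  entryTab <- getdf("entry", c(id = "id", title = "title", summary = "summary"),
                    c(id = "c", title = "c", summary = "c"))
  id <- if (nrow(entryTab)) entryTab$id[[1L]] else blk@name
  title <- if (nrow(entryTab) && !is.na(entryTab$title[[1L]])) entryTab$title[[1L]] else ""
  summary <- if (nrow(entryTab)) entryTab$summary[[1L]] else NA_character_

  authorsTab <- getdf("audit_author", c(ordinal = "ordinal", name = "name"),
                      c(ordinal = "i", name = "c"))
  authors <- if (nrow(authorsTab)) authorsTab$name[order(authorsTab$ordinal)] else character(0)

  entTab <- getdf("entity",
                  c(id = "id", kind = "type", polymer_type = "polymer_type",
                    description = "description"),
                  c(id = "c", kind = "c", polymer_type = "c", description = "c"))
  seqTab <- getdf("entity_seq",
                  c(entity_id = "entity_id", num = "num", comp_id = "comp_id"),
                  c(entity_id = "c", num = "i", comp_id = "c"))
  ents <- lapply(seq_len(nrow(entTab)), function(i) {
    rows <- seqTab[seqTab$entity_id == entTab$id[[i]], , drop = FALSE]
    list(id = entTab$id[[i]], kind = entTab$kind[[i]],
         polymer_type = entTab$polymer_type[[i]],
         sequence = rows$comp_id[order(rows$num)],
         description = entTab$description[[i]])
  })

  tabs <- list()
  for (lay in .categoryLayout)
    tabs[[lay$slot]] <- getdf(lay$category, lay$items, .entrySchemas[[lay$slot]])

  extras <- unname(cats[setdiff(names(cats), .knownCategories)])
  do.call(ihmEntry, c(list(id = id, title = title, summary = summary,
                           authors = authors, entities = ents, extras = extras),
                      tabs))
}
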