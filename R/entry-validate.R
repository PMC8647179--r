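## Referential closure over the entry object graph: every reference in every
## collection must resolve within the entry. Violations are findings, not
## exceptions, so curation code can report them all at once.

refFinding <- function(object, field, target) {
  data.frame(object = object, field = field, target = target,
             message = sprintf("%s: field '%s' references missing target '%s'",
                               object, field, target),
             stringsAsFactors = FALSE)
}

emptyRefFindings <- function() {
  data.frame(object = character(0), field = character(0), target = character(0),
             message = character(0), stringsAsFactors = FALSE)
}

#' Check referential integrity of an entry
#'
#' Walks every reference field in every collection (parent--child
#' relationships between the entry's objects) and returns one finding per
#' dangling reference, naming the referring object, the field and the
#' missing target. An empty result means referential closure holds.
#'
#' @param entry an [IhmEntry-class]
#' @return data.frame with columns `object`, `field`, `target`, `message`
#' @export
validateReferentialIntegrity <- function(entry) {
  out <- list()
  note <- function(object, field, targets, pool) {
    miss <- !is.na(targets) & !targets %in% pool
    for (i in which(miss))
      out[[length(out) + 1L]] <<- refFinding(object[[i]], field, targets[[i]])
  }
  entityIds <- vapply(entry@entities, function(e) e$id, character(1))
  asymIds <- entry@asyms$id
  lab <- function(kind, ids) sprintf("%s '%s'", kind, ids)

  note(lab("asym", entry@asyms$id), "entity_ref", entry@asyms$entity_ref, entityIds)
  note(lab("assembly", entry@assemblies$id), "asym_ref",
       entry@assemblies$asym_ref, asymIds)
  note(lab("representation", entry@representations$id), "asym_ref",
       entry@representations$asym_ref, asymIds)
  note(lab("representation", entry@representations$id), "starting_model_ref",
       entry@representations$starting_model_ref, entry@startingModels$id)
  note(lab("model", entry@models$id), "assembly_ref",
       entry@models$assembly_ref, entry@assemblies$id)
  note(lab("model", entry@models$id), "representation_ref",
       entry@models$representation_ref, entry@representations$id)
  note(lab("model", entry@models$id), "protocol_ref",
       entry@models$protocol_ref, entry@protocolSteps$protocol_id)
  note(lab("atom", seq_len(nrow(entry@atoms))), "model_ref",
       entry@atoms$model_ref, entry@models$id)
  note(lab("atom", seq_len(nrow(entry@atoms))), "asym_ref",
       entry@atoms$asym_ref, asymIds)
  note(lab("sphere", seq_len(nrow(entry@spheres))), "model_ref",
       entry@spheres$model_ref, entry@models$id)
  note(lab("sphere", seq_len(nrow(entry@spheres))), "asym_ref",
       entry@spheres$asym_ref, asymIds)
  note(lab("model_group_link", seq_len(nrow(entry@modelGroupLinks))), "group_id",
       entry@modelGroupLinks$group_id, entry@modelGroups$id)
  note(lab("model_group_link", seq_len(nrow(entry@modelGroupLinks))), "model_id",
       entry@modelGroupLinks$model_id, entry@models$id)
  note(lab("state_link", seq_len(nrow(entry@stateLinks))), "state_id",
       entry@stateLinks$state_id, entry@states$id)
  note(lab("state_link", seq_len(nrow(entry@stateLinks))), "group_id",
       entry@stateLinks$group_id, entry@modelGroups$id)
  note(lab("state_group_link", seq_len(nrow(entry@stateGroupLinks))), "state_group_id",
       entry@stateGroupLinks$state_group_id, entry@stateGroups$id)
  note(lab("state_group_link", seq_len(nrow(entry@stateGroupLinks))), "state_id",
       entry@stateGroupLinks$state_id, entry@states$id)
  note(lab("ordered_step", seq_len(nrow(entry@orderedSteps))), "process_id",
       entry@orderedSteps$process_id, entry@ordered$id)
  note(lab("ordered_step", seq_len(nrow(entry@orderedSteps))), "from_group_id",
       entry@orderedSteps$from_group_id, entry@modelGroups$id)
  note(lab("ordered_step", seq_len(nrow(entry@orderedSteps))), "to_group_id",
       entry@orderedSteps$to_group_id, entry@modelGroups$id)
  note(lab("ensemble", entry@ensembles$id), "group_ref",
       entry@ensembles$group_ref, entry@modelGroups$id)
  note(lab("starting_model", entry@startingModels$id), "asym_ref",
       entry@startingModels$asym_ref, asymIds)
  note(lab("starting_model", entry@startingModels$id), "dataset_ref",
       entry@startingModels$dataset_ref, entry@datasets$id)
  note(lab("crosslink", entry@crosslinks$id), "entity_ref_1",
       entry@crosslinks$entity_ref_1, entityIds)
  note(lab("crosslink", entry@crosslinks$id), "entity_ref_2",
       entry@crosslinks$entity_ref_2, entityIds)
  note(lab("crosslink", entry@crosslinks$id), "asym_ref_1",
       entry@crosslinks$asym_ref_1, asymIds)
  note(lab("crosslink", entry@crosslinks$id), "asym_ref_2",
       entry@crosslinks$asym_ref_2, asymIds)
  note(lab("crosslink", entry@crosslinks$id), "dataset_ref",
       entry@crosslinks$dataset_ref, entry@datasets$id)
  note(lab("fit_metric", seq_len(nrow(entry@fitMetrics))), "dataset_ref",
       entry@fitMetrics$dataset_ref, entry@datasets$id)
  note(lab("fit_metric", seq_len(nrow(entry@fitMetrics))), "model_ref",
       entry@fitMetrics$model_ref, entry@models$id)
  note(lab("protocol_step", seq_len(nrow(entry@protocolSteps))), "software_ref",
       entry@protocolSteps$software_ref, entry@software$id)
  if (nrow(entry@protocolSteps)) {
    refs <- strsplit(ifelse(is.na(entry@protocolSteps$dataset_refs), "",
                            entry@protocolSteps$dataset_refs), ",", fixed = TRUE)
    for (i in seq_along(refs)) {
      tgt <- trimws(refs[[i]]); tgt <- tgt[nzchar(tgt)]
      note(rep(sprintf("protocol_step '%s'", i), length(tgt)), "dataset_refs",
           tgt, entry@datasets$id)
    }
  }
  note(lab("citation_author", seq_len(nrow(entry@citationAuthors))), "citation_ref",
       entry@citationAuthors$citation_ref, entry@citations$id)
  note(lab("seq_reference", seq_len(nrow(entry@seqReferences))), "entity_ref",
       entry@seqReferences$entity_ref, entityIds)

  if (!length(out)) return(emptyRefFindings())
  do.call(rbind, out)
}
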