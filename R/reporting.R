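## Validation-report payloads: model composition and cross-link restraint
## satisfaction. Satisfaction is evaluated for upper-bound distance
## restraints; lower-bound and harmonic forms are stored and reported as
## not evaluated. The representative point of a cross-linked residue falls
## back along atom (by-atom restraints) -> CA atom -> covering sphere
## center, with no radius correction on sphere distances.

#' CompositionSummary: model-composition report payload
#'
#' @slot n_entities,n_asyms,n_models,n_states,n_model_groups counts
#' @slot residues_total residues over all asym units (entity length each)
#' @slot residues_atomic residues with at least one atom in any model
#' @slot residues_coarse residues covered by a sphere and not atomic
#' @slot atomic_fraction residues_atomic / max(residues modeled, 1)
#' @slot n_spheres,n_atoms distinct coarse-grained beads / atoms (across
#'   models, counted once per representation position)
#' @export
setClass("CompositionSummary",
  representation(n_entities = "integer", n_asyms = "integer",
                 n_models = "integer", n_states = "integer",
                 n_model_groups = "integer", residues_total = "integer",
                 residues_atomic = "integer", residues_coarse = "integer",
                 atomic_fraction = "numeric", n_spheres = "integer",
                 n_atoms = "integer"))

setValidity("CompositionSummary", function(object) {
  msgs <- character(0)
  if (object@residues_atomic + object@residues_coarse > object@residues_total)
    msgs <- c(msgs, "atomic + coarse residues cannot exceed the total")
  modeled <- object@residues_atomic + object@residues_coarse
  if (abs(object@atomic_fraction -
          object@residues_atomic / max(modeled, 1L)) > 1e-9)
    msgs <- c(msgs, "atomic_fraction inconsistent with residue counts")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CompositionSummary", function(object) {
  cat(sprintf("CompositionSummary: %d entities, %d chains, %d models, %d states\n",
              object@n_entities, object@n_asyms, object@n_models, object@n_states))
  cat(sprintf("  residues: %d total, %d atomic, %d coarse (atomic fraction %.2f)\n",
              object@residues_total, object@residues_atomic,
              object@residues_coarse, object@atomic_fraction))
  cat(sprintf("  %d atoms, %d spheres (distinct positions)\n",
              object@n_atoms, object@n_spheres))
})

#' Model-composition summary of an entry
#'
#' A residue counts as atomic if any atom with its residue index exists in
#' any model, and as coarse-grained if it is covered by a sphere and not
#' atomic; totals come from entity sequence lengths over all asym units.
#' Atom and sphere counts are distinct representation positions (not
#' multiplied by the number of models).
#'
#' @param entry an [IhmEntry-class] with referential integrity
#' @return a [CompositionSummary-class]
#' @export
modelComposition <- function(entry) {
  total <- 0L; atomic <- 0L; coarse <- 0L
  for (i in seq_len(nrow(entry@asyms))) {
    aid <- entry@asyms$id[[i]]
    ent <- entityById(entry, entry@asyms$entity_ref[[i]])
    len <- length(ent$sequence)
    total <- total + len
    atomSeq <- unique(entry@atoms$seq_id[entry@atoms$asym_ref == aid])
    sph <- entry@spheres[entry@spheres$asym_ref == aid, , drop = FALSE]
    covered <- rep(FALSE, len)
    for (j in seq_len(nrow(sph)))
      covered[seq(sph$seq_begin[[j]], min(sph$seq_end[[j]], len))] <- TRUE
    covered[atomSeq] <- FALSE     # coarse = covered by a sphere and not atomic
    atomic <- atomic + length(atomSeq)
    coarse <- coarse + sum(covered)
  }
  modeled <- atomic + coarse
  nSpheres <- nrow(unique(entry@spheres[c("asym_ref", "seq_begin", "seq_end")]))
  nAtoms <- nrow(unique(entry@atoms[c("asym_ref", "seq_id", "atom_name")]))
  new("CompositionSummary",
      n_entities = length(entry@entities), n_asyms = nrow(entry@asyms),
      n_models = nrow(entry@models), n_states = nrow(entry@states),
      n_model_groups = nrow(entry@modelGroups),
      residues_total = as.integer(total), residues_atomic = as.integer(atomic),
      residues_coarse = as.integer(coarse),
      atomic_fraction = atomic / max(modeled, 1L),
      n_spheres = as.integer(nSpheres), n_atoms = as.integer(nAtoms))
}

#' SatisfactionSummary: cross-link satisfaction report payload
#'
#' @slot n_groups evaluated ambiguity groups
#' @slot n_satisfied,n_violated counts (`n_satisfied + n_violated = n_groups`)
#' @slot threshold_policy human-readable description of the evaluation policy
#' @export
setClass("SatisfactionSummary",
  representation(n_groups = "integer", n_satisfied = "integer",
                 n_violated = "integer", threshold_policy = "character"))

setValidity("SatisfactionSummary", function(object) {
  if (object@n_satisfied + object@n_violated != object@n_groups)
    "n_satisfied + n_violated must equal n_groups" else TRUE
})

setMethod("show", "SatisfactionSummary", function(object) {
  cat(sprintf("SatisfactionSummary: %d group(s), %d satisfied, %d violated\n",
              object@n_groups, object@n_satisfied, object@n_violated))
  cat(" ", object@threshold_policy, "\n")
})

## Hashed coordinate index for representative-point lookups; built once per
## satisfaction run. Atom lookups are exact-key; sphere coverage scans the
## (model, asym)-bucketed bead list.
buildCoordIndex <- function(entry) {
  atomKey <- new.env(parent = emptyenv(), size = max(16L, nrow(entry@atoms)))
  at <- entry@atoms
  if (nrow(at)) {
    keys <- paste(at$model_ref, at$asym_ref, at$seq_id, at$atom_name, sep = "\r")
    for (i in seq_along(keys))
      if (is.null(atomKey[[keys[[i]]]])) atomKey[[keys[[i]]]] <- i
  }
  sphereBuckets <- new.env(parent = emptyenv())
  sp <- entry@spheres
  if (nrow(sp)) {
    bk <- paste(sp$model_ref, sp$asym_ref, sep = "\r")
    for (i in seq_along(bk)) sphereBuckets[[bk[[i]]]] <- c(sphereBuckets[[bk[[i]]]], i)
  }
  list(atomKey = atomKey, sphereBuckets = sphereBuckets, atoms = at, spheres = sp,
       asymsOfEntity = split(entry@asyms$id, entry@asyms$entity_ref))
}

## representative points of one cross-link end in one model; a matrix of
## candidate coordinates (one row per resolvable asym candidate), or NULL
repPoints <- function(idx, modelId, entityRef, asymRef, seqId, atomName,
                      granularity) {
  asyms <- if (!is.na(asymRef)) asymRef else idx$asymsOfEntity[[entityRef]]
  pts <- list()
  for (aid in asyms) {
    if (identical(granularity, "by-atom") && !is.na(atomName)) {
      i <- idx$atomKey[[paste(modelId, aid, seqId, atomName, sep = "\r")]]
      if (!is.null(i)) {
        pts[[length(pts) + 1L]] <- c(idx$atoms$x[[i]], idx$atoms$y[[i]], idx$atoms$z[[i]])
        next
      }
    }
    i <- idx$atomKey[[paste(modelId, aid, seqId, "CA", sep = "\r")]]
    if (!is.null(i)) {
      pts[[length(pts) + 1L]] <- c(idx$atoms$x[[i]], idx$atoms$y[[i]], idx$atoms$z[[i]])
      next
    }
    for (i in idx$sphereBuckets[[paste(modelId, aid, sep = "\r")]]) {
      if (idx$spheres$seq_begin[[i]] <= seqId && idx$spheres$seq_end[[i]] >= seqId) {
        pts[[length(pts) + 1L]] <- c(idx$spheres$x[[i]], idx$spheres$y[[i]],
                                     idx$spheres$z[[i]])
        break
      }
    }
  }
  if (!length(pts)) NULL else do.call(rbind, pts)
}

#' Cross-link restraint satisfaction over an ensemble
#'
#' Restraints sharing a `group_id` form one ambiguity group. Per model, the
#' group distance combines member pair distances by the group's
#' conditionality (`any` takes the minimum, `all` the maximum); a pair
#' distance is the Euclidean distance between representative points (the
#' named atom for by-atom restraints when present, else the residue's CA
#' atom, else the center of the sphere covering the residue). A group is
#' satisfied in a model iff its distance is within the threshold
#' (upper-bound form). Under the default `any-model` ensemble rule a group
#' is satisfied iff it is satisfied in at least one model; `all-models`
#' requires every model. Groups with an end not represented by any atom or
#' sphere yield an "unrepresented cross-link end" finding and are excluded
#' from the counts; non-upper-bound groups are reported as not evaluated.
#'
#' @param entry an [IhmEntry-class] with at least one model and cross-link
#' @param policy list with `ensemble_rule`: `"any-model"` or `"all-models"`
#' @return `list(summary=, outcomes=, findings=, not_evaluated=)`;
#'   `outcomes` has columns `group_id`, `min_distance`, `satisfied`,
#'   `best_model_ref`
#' @export
crosslinkSatisfaction <- function(entry, policy = list(ensemble_rule = "any-model")) {
  rule <- match.arg(policy$ensemble_rule, c("any-model", "all-models"))
  if (!nrow(entry@models)) stop("entry has no models", call. = FALSE)
  if (!nrow(entry@crosslinks)) stop("entry has no cross-links", call. = FALSE)
  xl <- entry@crosslinks
  modelIds <- entry@models$id
  idx <- buildCoordIndex(entry)
  groups <- unique(xl$group_id)
  outcomes <- list(); findings <- list(); notEval <- character(0)
  for (g in groups) {
    members <- xl[xl$group_id == g, , drop = FALSE]
    evalMembers <- members[members$restraint_form == "upper-bound", , drop = FALSE]
    if (!nrow(evalMembers)) { notEval <- c(notEval, g); next }
    cond <- evalMembers$conditionality[[1L]]
    threshold <- evalMembers$threshold[[1L]]
    perModel <- rep(NA_real_, length(modelIds))
    unrep <- FALSE
    for (mi in seq_along(modelIds)) {
      dists <- numeric(0)
      for (k in seq_len(nrow(evalMembers))) {
        r <- evalMembers[k, ]
        p1 <- repPoints(idx, modelIds[[mi]], r$entity_ref_1, r$asym_ref_1,
                        r$seq_id_1, r$atom_name_1, r$granularity)
        p2 <- repPoints(idx, modelIds[[mi]], r$entity_ref_2, r$asym_ref_2,
                        r$seq_id_2, r$atom_name_2, r$granularity)
        if (is.null(p1) || is.null(p2)) { unrep <- TRUE; break }
        best <- Inf
        for (u in seq_len(nrow(p1)))
          for (v in seq_len(nrow(p2)))
            best <- min(best, sqrt(sum((p1[u, ] - p2[v, ])^2)))
        dists <- c(dists, best)
      }
      if (unrep) break
      perModel[[mi]] <- if (cond == "any") min(dists) else max(dists)
    }
    if (unrep) {
      findings[[length(findings) + 1L]] <- data.frame(
        group_id = g, message = sprintf(
          "unrepresented cross-link end in group '%s': no atom or sphere covers an end", g),
        stringsAsFactors = FALSE)
      next
    }
    satisfiedPerModel <- perModel <= threshold
    satisfied <- if (rule == "any-model") any(satisfiedPerModel)
                 else all(satisfiedPerModel)
    best <- which.min(perModel)
    outcomes[[length(outcomes) + 1L]] <- data.frame(
      group_id = g, min_distance = perModel[[best]], satisfied = satisfied,
      best_model_ref = modelIds[[best]], stringsAsFactors = FALSE)
  }
  outcomes <- if (length(outcomes)) do.call(rbind, outcomes) else
    data.frame(group_id = character(0), min_distance = numeric(0),
               satisfied = logical(0), best_model_ref = character(0),
               stringsAsFactors = FALSE)
  findings <- if (length(findings)) do.call(rbind, findings) else
    data.frame(group_id = character(0), message = character(0),
               stringsAsFactors = FALSE)
  summary <- new("SatisfactionSummary",
                 n_groups = nrow(outcomes),
                 n_satisfied = as.integer(sum(outcomes$satisfied)),
                 n_violated = as.integer(sum(!outcomes$satisfied)),
                 threshold_policy = sprintf(
                   "upper-bound restraints; representative point atom>CA>sphere center; ensemble rule %s",
                   rule))
  list(summary = summary, outcomes = outcomes, findings = findings,
       not_evaluated = notEval)
}
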