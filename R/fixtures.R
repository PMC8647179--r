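## Deterministic synthetic-entry generator. Emulates the variety the archive
## holds -- multi-scale chains (atomic N-terminal region as CA atoms on a
## self-avoiding random walk, the remainder as coarse-grained beads),
## multi-state model groups, optional ordered processes, and cross-link
## restraints placed by construction at 0.5x (satisfied) and 1.5x (violated)
## of their distance threshold in every model. Every generated quantity is
## echoed in a ground-truth record so production operations can be tested
## for exact parameter recovery.

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic-entry generator
#'
#' Defaults describe the reference fixture: one 100-residue protein chain,
#' 30% atomic (by-residue CA trace) and 70% coarse-grained in 10-residue
#' beads, with 15 satisfied and 5 violated cross-links at a 25 A
#' upper-bound threshold (a typical DSS cross-linker cutoff).
#'
#' @param n_entities number of polymer entities (one asym unit each), >= 1
#' @param chain_length residues per entity, >= 1
#' @param n_models number of deposited models, >= 1
#' @param atomic_fraction fraction of each chain modeled atomically, in [0,1]
#' @param sphere_residues_per_bead residues per coarse-grained bead, >= 1
#' @param n_states number of conformational states, >= 1
#' @param ordered add a two-step ordered process (requires n_states >= 2)
#' @param n_crosslinks_satisfied cross-link groups placed at 0.5x threshold
#' @param n_crosslinks_violated cross-link groups placed at 1.5x threshold
#' @param crosslink_threshold upper-bound distance threshold in Angstroms
#' @param seed integer seed; the generator is deterministic for a fixed seed
#' @return a `ToyConfig` list
#' @export
toyConfig <- function(n_entities = 1L, chain_length = 100L, n_models = 1L,
                      atomic_fraction = 0.3, sphere_residues_per_bead = 10L,
                      n_states = 1L, ordered = FALSE,
                      n_crosslinks_satisfied = 15L, n_crosslinks_violated = 5L,
                      crosslink_threshold = 25, seed = 1L) {
  stopifnot(n_entities >= 1, chain_length >= 1, n_models >= 1,
            atomic_fraction >= 0, atomic_fraction <= 1,
            sphere_residues_per_bead >= 1, n_states >= 1,
            n_crosslinks_satisfied >= 0, n_crosslinks_violated >= 0,
            crosslink_threshold > 0)
  if (ordered && n_states < 2)
    stop("an ordered process needs at least 2 states", call. = FALSE)
  structure(list(n_entities = as.integer(n_entities),
                 chain_length = as.integer(chain_length),
                 n_models = as.integer(n_models),
                 atomic_fraction = atomic_fraction,
                 sphere_residues_per_bead = as.integer(sphere_residues_per_bead),
                 n_states = as.integer(n_states), ordered = isTRUE(ordered),
                 n_crosslinks_satisfied = as.integer(n_crosslinks_satisfied),
                 n_crosslinks_violated = as.integer(n_crosslinks_violated),
                 crosslink_threshold = crosslink_threshold,
                 seed = as.integer(seed)),
            class = "ToyConfig")
}

#' Draw a random valid ToyConfig
#'
#' Used by property-style tests; sizes stay small enough that all derived
#' checks run quickly.
#' @param seed integer seed
#' @return a `ToyConfig`
#' @export
randomToyConfig <- function(seed) {
  withSeed(seed, {
    nStates <- sample(1:3, 1)
    bead <- sample(4:12, 1)
    L <- sample(40:120, 1)
    af <- sample(c(0, 0.2, 0.3, 0.5, 0.8, 1), 1)
    nA <- floor(af * L)
    nBeads <- ceiling((L - nA) / bead)
    sites <- nA + nBeads
    nxl <- max(0L, min(sites %/% 2L - 1L, sample(0:12, 1)))
    nsat <- sample(0:nxl, 1)
    toyConfig(n_entities = sample(1:2, 1), chain_length = L,
              n_models = sample(1:4, 1), atomic_fraction = af,
              sphere_residues_per_bead = bead, n_states = nStates,
              ordered = nStates >= 2 && runif(1) < 0.5,
              n_crosslinks_satisfied = nsat, n_crosslinks_violated = nxl - nsat,
              crosslink_threshold = sample(c(20, 25, 30), 1),
              seed = seed + 1000L)
  })
}

## random walk with approximate self-avoidance: rejection up to 100 tries
## against a 3.0 A exclusion radius, then relax
walkStep <- function(prev, pts, step) {
  for (try in 1:100) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    cand <- prev + step * u
    if (!nrow(pts) || min(colSums((t(pts) - cand)^2)) > 9) return(cand)
  }
  cand
}

#' Generate a synthetic deposition entry with ground truth
#'
#' Builds a complete, referentially closed [IhmEntry-class] from a
#' [toyConfig()]: sequences, multi-scale representation, coordinates for
#' every model, state/model-group structure, an optional ordered process,
#' an ensemble, datasets, a starting model, software, citation and protocol
#' metadata, and cross-links placed by construction at 0.5x / 1.5x of the
#' threshold in every model. Deterministic for a fixed config seed.
#'
#' @param config a `ToyConfig`
#' @return `list(entry=, truth=)` where `truth` echoes the config and the
#'   expected derived facts, composition numbers and satisfaction counts
#' @export
generateEntry <- function(config) {
  stopifnot(inherits(config, "ToyConfig"))
  L <- config$chain_length
  nA <- as.integer(floor(config$atomic_fraction * L))
  nBeads <- if (nA < L) as.integer(ceiling((L - nA) / config$sphere_residues_per_bead)) else 0L
  nxl <- config$n_crosslinks_satisfied + config$n_crosslinks_violated
  sitesPerEntity <- nA + nBeads
  ## each cross-link moves one unique endpoint; anchors may be shared but must
  ## not themselves be moved, so nxl + 1 anchorable sites are required
  if (nxl > 0L && nxl + 1L > sitesPerEntity * config$n_entities)
    stop("impossible geometry: ", nxl, " cross-links need ", nxl + 1L,
         " distinct sites but only ", sitesPerEntity * config$n_entities,
         " exist", call. = FALSE)

  withSeed(config$seed, {
    asymIds <- if (config$n_entities <= 26) LETTERS[seq_len(config$n_entities)]
               else paste0("A", seq_len(config$n_entities))
    entIds <- paste0("e", seq_len(config$n_entities))
    seqs <- lapply(seq_len(config$n_entities), function(i)
      sample(names(AA_THREE_TO_ONE)[1:20], L, replace = TRUE))
    ents <- lapply(seq_len(config$n_entities), function(i)
      list(id = entIds[[i]], kind = "polymer", polymer_type = "protein",
           sequence = seqs[[i]],
           description = paste("synthetic chain", asymIds[[i]])))

    ## bead layout (identical across entities): residue ranges per bead
    beadRanges <- if (nBeads) {
      b <- seq(nA + 1L, L, by = config$sphere_residues_per_bead)
      cbind(begin = b, end = pmin(b + config$sphere_residues_per_bead - 1L, L))
    } else matrix(integer(0), ncol = 2, dimnames = list(NULL, c("begin", "end")))
    beadRadius <- round(2 * sqrt(config$sphere_residues_per_bead), 3)

    ## site table: one row per potential cross-link anchor
    sites <- do.call(rbind, lapply(seq_len(config$n_entities), function(e) {
      at <- if (nA) data.frame(entity = entIds[[e]], asym = asymIds[[e]],
                               seq = seq_len(nA), kind = "atom",
                               bead = NA_integer_, stringsAsFactors = FALSE)
            else NULL
      sp <- if (nBeads) data.frame(entity = entIds[[e]], asym = asymIds[[e]],
                                   seq = as.integer(beadRanges[, "begin"]),
                                   kind = "sphere", bead = seq_len(nBeads),
                                   stringsAsFactors = FALSE)
            else NULL
      rbind(at, sp)
    }))
    ## moved endpoints are unique; anchors are drawn (with replacement) from
    ## the remaining sites so their positions are never overwritten
    if (nxl) {
      movedIdx <- sample(nrow(sites), nxl)
      rest <- setdiff(seq_len(nrow(sites)), movedIdx)
      anchorIdx <- rest[sample.int(length(rest), nxl, replace = TRUE)]
      pick <- sites[as.vector(rbind(anchorIdx, movedIdx)), , drop = FALSE]
    } else pick <- sites[0, ]

    atoms <- list(); spheres <- list()
    for (m in seq_len(config$n_models)) {
      mid <- paste0("m", m)
      coordA <- list(); coordS <- list()  # per (asym) coordinate stores
      for (e in seq_len(config$n_entities)) {
        pts <- matrix(numeric(0), ncol = 3)
        prev <- c((e - 1) * 150, 0, 0)
        atomXYZ <- matrix(NA_real_, nrow = nA, ncol = 3)
        for (i in seq_len(nA)) {
          prev <- walkStep(prev, pts, 3.8)
          pts <- rbind(pts, prev)
          atomXYZ[i, ] <- prev
        }
        beadXYZ <- matrix(NA_real_, nrow = nBeads, ncol = 3)
        for (i in seq_len(nBeads)) {
          prev <- walkStep(prev, pts, 2 * beadRadius)
          pts <- rbind(pts, prev)
          beadXYZ[i, ] <- prev
        }
        coordA[[asymIds[[e]]]] <- atomXYZ
        coordS[[asymIds[[e]]]] <- beadXYZ
      }
      ## place cross-link partners at exact distances (every model)
      for (k in seq_len(nxl)) {
        a <- pick[2L * k - 1L, ]; b <- pick[2L * k, ]
        d <- (if (k <= config$n_crosslinks_satisfied) 0.5 else 1.5) *
          config$crosslink_threshold
        posA <- if (a$kind == "atom") coordA[[a$asym]][a$seq, ]
                else coordS[[a$asym]][a$bead, ]
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        posB <- posA + d * u
        if (b$kind == "atom") coordA[[b$asym]][b$seq, ] <- posB
        else coordS[[b$asym]][b$bead, ] <- posB
      }
      for (e in seq_len(config$n_entities)) {
        aid <- asymIds[[e]]
        if (nA) atoms[[length(atoms) + 1L]] <- data.frame(
          model_ref = mid, asym_ref = aid, seq_id = seq_len(nA),
          comp_id = seqs[[e]][seq_len(nA)], atom_name = "CA", element = "C",
          x = round(coordA[[aid]][, 1], 3), y = round(coordA[[aid]][, 2], 3),
          z = round(coordA[[aid]][, 3], 3), stringsAsFactors = FALSE)
        if (nBeads) spheres[[length(spheres) + 1L]] <- data.frame(
          model_ref = mid, asym_ref = aid,
          seq_begin = as.integer(beadRanges[, "begin"]),
          seq_end = as.integer(beadRanges[, "end"]),
          x = round(coordS[[aid]][, 1], 3), y = round(coordS[[aid]][, 2], 3),
          z = round(coordS[[aid]][, 3], 3), radius = beadRadius,
          rmsf = NA_real_, stringsAsFactors = FALSE)
      }
    }

    G <- config$n_states
    groupOf <- function(m) ((m - 1L) %% G) + 1L
    links <- data.frame(group_id = paste0("g", groupOf(seq_len(config$n_models))),
                        model_id = paste0("m", seq_len(config$n_models)),
                        stringsAsFactors = FALSE)
    for (g in seq_len(G))  # recycle models so no group is empty
      if (!paste0("g", g) %in% links$group_id)
        links <- rbind(links, data.frame(
          group_id = paste0("g", g),
          model_id = paste0("m", ((g - 1L) %% config$n_models) + 1L)))
    popFrac <- floor(1000 / G) / 1000

    reps <- do.call(rbind, lapply(seq_len(config$n_entities), function(e) {
      at <- if (nA) data.frame(id = "rep1", asym_ref = asymIds[[e]],
                               seq_begin = 1L, seq_end = nA, mode = "atomic",
                               granularity = "by-residue", is_rigid = FALSE,
                               starting_model_ref = if (e == 1L) "sm1" else NA_character_,
                               stringsAsFactors = FALSE)
            else NULL
      sp <- if (nBeads) data.frame(id = "rep1", asym_ref = asymIds[[e]],
                                   seq_begin = nA + 1L, seq_end = L, mode = "sphere",
                                   granularity = "by-feature", is_rigid = FALSE,
                                   starting_model_ref = NA_character_,
                                   stringsAsFactors = FALSE)
            else NULL
      rbind(at, sp)
    }))

    crosslinks <- if (nxl) do.call(rbind, lapply(seq_len(nxl), function(k) {
      a <- pick[2L * k - 1L, ]; b <- pick[2L * k, ]
      data.frame(id = as.character(k), group_id = as.character(k),
                 entity_ref_1 = a$entity, asym_ref_1 = a$asym, seq_id_1 = a$seq,
                 atom_name_1 = NA_character_,
                 entity_ref_2 = b$entity, asym_ref_2 = b$asym, seq_id_2 = b$seq,
                 atom_name_2 = NA_character_, linker = "DSS",
                 threshold = config$crosslink_threshold,
                 restraint_form = "upper-bound", granularity = "by-residue",
                 conditionality = "any", dataset_ref = "ds1",
                 stringsAsFactors = FALSE)
    })) else NULL

    smEnd <- max(nA, 1L)
    entry <- ihmEntry(
      id = sprintf("SYN%04d", config$seed %% 10000L),
      title = "Synthetic multi-scale benchmark complex",
      summary = "Deterministic synthetic integrative structure for testing",
      authors = c("Doe, Jane", "Roe, Richard"),
      entities = ents,
      asyms = data.frame(id = asymIds, entity_ref = entIds),
      assemblies = data.frame(id = "asm1", asym_ref = asymIds,
                              seq_begin = 1L, seq_end = L),
      representations = reps,
      models = data.frame(id = paste0("m", seq_len(config$n_models)),
                          assembly_ref = "asm1", representation_ref = "rep1",
                          protocol_ref = "p1"),
      atoms = if (length(atoms)) do.call(rbind, atoms) else NULL,
      spheres = if (length(spheres)) do.call(rbind, spheres) else NULL,
      modelGroups = data.frame(id = paste0("g", seq_len(G)),
                               name = paste("models for state", seq_len(G))),
      modelGroupLinks = links,
      states = data.frame(id = paste0("s", seq_len(G)),
                          name = paste("state", seq_len(G)),
                          population_fraction = popFrac),
      stateLinks = data.frame(state_id = paste0("s", seq_len(G)),
                              group_id = paste0("g", seq_len(G))),
      stateGroups = data.frame(id = "sg1"),
      stateGroupLinks = data.frame(state_group_id = "sg1",
                                   state_id = paste0("s", seq_len(G))),
      ordered = if (config$ordered)
        data.frame(id = "o1", ordered_by = "time") else NULL,
      orderedSteps = if (config$ordered) data.frame(
        process_id = "o1", step_index = 1:2,
        from_group_id = c("g1", "g2"),
        to_group_id = c("g2", paste0("g", if (G >= 3) 3L else 1L))) else NULL,
      ensembles = data.frame(id = "ens1", group_ref = "g1",
                             num_models_total = config$n_models * 50L,
                             num_models_deposited =
                               sum(links$group_id == "g1"),
                             clustering_method = "k-means"),
      datasets = data.frame(
        id = c("ds1", "ds2", "ds3"),
        data_type = c("CX-MS", "3DEM", "X-ray"),
        db_name = c("ProteomeXchange", "EMDB", "PDB"),
        accession = c("PXD000001", "EMD-1001", "1ABC"),
        doi = NA_character_, file_path = NA_character_),
      startingModels = data.frame(id = "sm1", asym_ref = asymIds[[1L]],
                                  seq_begin = 1L, seq_end = smEnd,
                                  source_type = "experimental",
                                  dataset_ref = "ds3"),
      crosslinks = crosslinks,
      fitMetrics = data.frame(restraint_kind = "3DEM", dataset_ref = "ds2",
                              model_ref = "m1", metric_name = "cross-correlation",
                              metric_value = 0.85),
      protocolSteps = data.frame(
        protocol_id = "p1", step_index = 1:2,
        method_name = c("replica exchange sampling", "refinement"),
        num_models_begin = c(0L, config$n_models * 100L),
        num_models_end = c(config$n_models * 100L, config$n_models * 50L),
        multi_scale = nA > 0L && nBeads > 0L,
        multi_state = G >= 2L, ordered = config$ordered,
        software_ref = "sw1", dataset_refs = "ds1"),
      software = data.frame(id = "sw1", name = "IMP", version = "2.15",
                            classification = "integrative modeling",
                            location = "https://integrativemodeling.org"),
      citations = data.frame(id = "cit1",
                             title = "Integrative structure of a synthetic benchmark complex",
                             journal = "J. Synth. Struct. Biol.",
                             doi = "10.0000/synthetic.0001", pmid = NA_character_),
      citationAuthors = data.frame(citation_ref = "cit1", ordinal = 1:2,
                                   name = c("Doe, Jane", "Roe, Richard")))

    truth <- list(
      config = config,
      n_models = config$n_models,
      asym_ids = asymIds,
      sequences_three = stats::setNames(seqs, entIds),
      sequences_one = stats::setNames(
        vapply(seqs, function(s) paste(compOneLetter(s), collapse = ""),
               character(1)), entIds),
      residues_total = config$n_entities * L,
      residues_atomic = config$n_entities * nA,
      residues_coarse = config$n_entities * (L - nA),
      n_spheres = config$n_entities * nBeads,
      n_atoms = config$n_entities * nA,
      atomic_fraction = (config$n_entities * nA) /
        max(config$n_entities * L, 1L),
      n_states = G, n_model_groups = G,
      n_satisfied = config$n_crosslinks_satisfied,
      n_violated = config$n_crosslinks_violated,
      crosslink_sites = if (nxl) pick else NULL)
    list(entry = entry, truth = truth)
  })
}

#' Reduce an entry to a bare model-coordinate upload
#'
#' Depositor uploads are typically modeling-software output: coordinates and
#' structural organisation without restraints, citations or author metadata
#' (those are added later in the workflow). This strips a complete fixture
#' entry down to that shape for workflow tests.
#'
#' @param entry a complete [IhmEntry-class]
#' @return the reduced [IhmEntry-class]
#' @export
stripToModelUpload <- function(entry) {
  entry@crosslinks <- emptyTyped(.entrySchemas$crosslinks)
  entry@fitMetrics <- emptyTyped(.entrySchemas$fitMetrics)
  entry@seqReferences <- emptyTyped(.entrySchemas$seqReferences)
  entry@citations <- emptyTyped(.entrySchemas$citations)
  entry@citationAuthors <- emptyTyped(.entrySchemas$citationAuthors)
  entry@authors <- character(0)
  entry
}

## value pool for round-trip stress documents: quoting hazards, sentinels as
## text, embedded newlines (never a line starting with ';'), unicode
.stressValues <- c(
  "plain", "two words", "it's", "say \"hi\"", "?", ".", "", "don't stop",
  "line one\nline two", "_underscore", "#hash", "data_x", "loop_", "5.5",
  "-3e4", "trailing'", "'leading", "a\"b'c", "tab\there", "[bracket]",
  "$dollar", "semi ; colon", "quote' inside", "both ' and \" marks",
  "multi\nline\nvalue", "  padded  ", "été")

#' Generate a random mmCIF document for round-trip stress testing
#'
#' Random block/category/item names, values drawn from a quoting-stress pool
#' (whitespace, quote characters, sentinels-as-text, embedded newlines),
#' random unknown/inapplicable flags, and loops up to 50 rows by 10 columns.
#'
#' @param seed integer seed
#' @return a [CifDocument-class]
#' @export
generateRandomDocument <- function(seed) {
  withSeed(seed, {
    nblocks <- sample(1:2, 1)
    usedBlocks <- character(0)
    blocks <- lapply(seq_len(nblocks), function(b) {
      nm <- paste0("blk", b, paste(sample(letters, 3), collapse = ""))
      ncats <- sample(1:5, 1)
      catNames <- paste0("cat", seq_len(ncats), "_",
                         replicate(ncats, paste(sample(letters, 2), collapse = "")))
      cats <- lapply(catNames, function(cn) {
        nitems <- sample(1:10, 1)
        nrows <- if (stats::runif(1) < 0.4) 1L else sample(1:50, 1)
        items <- paste0("it", seq_len(nitems))
        vals <- matrix(sample(.stressValues, nitems * nrows, replace = TRUE),
                       nrow = nrows)
        flags <- matrix(sample(c(0L, 0L, 0L, 1L, 2L), nitems * nrows,
                               replace = TRUE), nrow = nrows)
        vals[flags != CIF_TEXT] <- NA_character_
        new("CifCategory", name = cn, items = items, values = vals, flags = flags)
      })
      cifBlock(nm, cats)
    })
    cifDocument(blocks)
  })
}

#' Emit the cross-link CSV for an entry's restraints
#'
#' Writes the documented harvest template; ingesting the result with
#' [parseRestraintCsv()] reproduces the entry's cross-link set exactly
#' (asym units are re-resolved, which is unambiguous when each entity has
#' one chain, as in generated fixtures).
#'
#' @param entry an [IhmEntry-class]
#' @param truth optional ground-truth record (unused; accepted for symmetry)
#' @return CSV text (header always present)
#' @export
generateCrosslinkCsv <- function(entry, truth = NULL) {
  xl <- entry@crosslinks
  compAt <- function(eid, seq) {
    e <- entityById(entry, eid)
    if (is.null(e) || seq > length(e$sequence)) NA_character_ else e$sequence[[seq]]
  }
  rows <- vapply(seq_len(nrow(xl)), function(i) paste(c(
    xl$group_id[[i]], xl$entity_ref_1[[i]], xl$seq_id_1[[i]],
    compAt(xl$entity_ref_1[[i]], xl$seq_id_1[[i]]),
    if (is.na(xl$atom_name_1[[i]])) "" else xl$atom_name_1[[i]],
    xl$entity_ref_2[[i]], xl$seq_id_2[[i]],
    compAt(xl$entity_ref_2[[i]], xl$seq_id_2[[i]]),
    if (is.na(xl$atom_name_2[[i]])) "" else xl$atom_name_2[[i]],
    xl$linker[[i]], fmtNum(xl$threshold[[i]]), xl$restraint_form[[i]],
    xl$conditionality[[i]], xl$dataset_ref[[i]]), collapse = ","),
    character(1))
  paste(c(paste(crosslinkCsvColumns(), collapse = ","), rows, ""),
        collapse = "\n")
}
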