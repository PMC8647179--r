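## Automated facts derived from uploaded model coordinates: the harvesting
## agent's "step 3" processing. Works on the syntax-level document so that it
## can also handle partial uploads that lack entity declarations (sequences
## are then reconstructed from per-residue atom records with gaps marked).

## 3-letter -> 1-letter amino-acid component codes (standard residues plus
## common variants); unknown components map to X.
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q", GLU = "E",
  GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "U", PYL = "O", UNK = "X")

#' One-letter code for 3-letter component codes
#' @param comp character vector of 3-letter component codes (`NA` allowed)
#' @return character vector; unknown components become `"X"`, `NA` becomes `"-"`
#' @export
compOneLetter <- function(comp) {
  out <- unname(AA_THREE_TO_ONE[toupper(comp)])
  out[is.na(out) & !is.na(comp)] <- "X"
  out[is.na(comp)] <- "-"
  out
}

#' DerivedFacts: coordinate-derived deposition facts
#'
#' @slot n_models number of distinct model ids across atom and sphere records
#' @slot asym_ids chain identifiers present
#' @slot sequences named list (by entity id) of `list(three=, one=)` sequences;
#'   reconstructed sequences mark unobserved positions with `NA` / `-`
#' @slot has_atoms,has_spheres logical flags
#' @slot modeled_ranges named list (by asym id) of two-column matrices of
#'   merged inclusive residue ranges covered by atoms or spheres
#' @export
setClass("DerivedFacts",
  representation(n_models = "integer", asym_ids = "character",
                 sequences = "list", has_atoms = "logical",
                 has_spheres = "logical", modeled_ranges = "list"))

setMethod("show", "DerivedFacts", function(object) {
  cat(sprintf("DerivedFacts: %d model(s), %d asym unit(s), atoms=%s, spheres=%s\n",
              object@n_models, length(object@asym_ids),
              object@has_atoms, object@has_spheres))
  for (nm in names(object@sequences))
    cat(sprintf("  entity %s: %d residues\n", nm,
                length(object@sequences[[nm]]$three)))
})

mergeRanges <- function(begin, end) {
  if (!length(begin)) return(matrix(integer(0), ncol = 2,
                                    dimnames = list(NULL, c("begin", "end"))))
  o <- order(begin, end)
  begin <- begin[o]; end <- end[o]
  rb <- begin[[1]]; re <- end[[1]]; out <- list()
  for (i in seq_along(begin)[-1]) {
    if (begin[[i]] <= re + 1L) re <- max(re, end[[i]])
    else { out[[length(out) + 1L]] <- c(rb, re); rb <- begin[[i]]; re <- end[[i]] }
  }
  out[[length(out) + 1L]] <- c(rb, re)
  m <- do.call(rbind, out)
  dimnames(m) <- list(NULL, c("begin", "end"))
  m
}

#' Derive deposition facts from model coordinates
#'
#' Emulates the automated processing agent of the harvesting workflow:
#' counts submitted models, lists the components of the structural assembly
#' and recovers the polymeric sequences of the macromolecules modeled.
#' Sequences come from the entity categories when present; otherwise they
#' are reconstructed from per-residue atom records, with unobserved
#' positions marked as gaps.
#'
#' @param doc a [CifDocument-class] containing coordinate categories
#' @return a [DerivedFacts-class]
#' @export
deriveEntryFacts <- function(doc) {
  if (!length(doc@blocks)) stop("empty document", call. = FALSE)
  blk <- doc@blocks[[1L]]
  cats <- blk@categories
  hasAtoms <- "atom_site" %in% names(cats)
  hasSpheres <- "sphere_site" %in% names(cats)
  if (!hasAtoms && !hasSpheres)
    stop("no models found: document lacks coordinate categories", call. = FALSE)

  atoms <- if (hasAtoms)
    categoryToDf(cats[["atom_site"]],
                 .categoryLayout[[which(vapply(.categoryLayout, `[[`, character(1),
                                               "category") == "atom_site")]]$items,
                 .entrySchemas$atoms, blk@name)
  else emptyTyped(.entrySchemas$atoms)
  spheres <- if (hasSpheres)
    categoryToDf(cats[["sphere_site"]],
                 .categoryLayout[[which(vapply(.categoryLayout, `[[`, character(1),
                                               "category") == "sphere_site")]]$items,
                 .entrySchemas$spheres, blk@name)
  else emptyTyped(.entrySchemas$spheres)

  usedAsyms <- unique(c(atoms$asym_ref, spheres$asym_ref))
  asymEntity <- NULL
  if ("struct_asym" %in% names(cats)) {
    asymTab <- categoryToDf(cats[["struct_asym"]],
                            c(id = "id", entity_ref = "entity_id"),
                            c(id = "c", entity_ref = "c"), blk@name)
    undeclared <- setdiff(usedAsyms, asymTab$id)
    if (length(undeclared))
      stop("coordinate records reference undeclared asym id(s): ",
           paste(undeclared, collapse = ", "), call. = FALSE)
    asymIds <- asymTab$id
    asymEntity <- stats::setNames(asymTab$entity_ref, asymTab$id)
  } else {
    asymIds <- sort(usedAsyms)
    asymEntity <- stats::setNames(asymIds, asymIds)  # each chain its own entity
  }

  nModels <- length(unique(c(atoms$model_ref, spheres$model_ref)))

  sequences <- list()
  if (all(c("entity", "entity_seq") %in% names(cats))) {
    entTab <- categoryToDf(cats[["entity"]], c(id = "id"), c(id = "c"), blk@name)
    seqTab <- categoryToDf(cats[["entity_seq"]],
                           c(entity_id = "entity_id", num = "num", comp_id = "comp_id"),
                           c(entity_id = "c", num = "i", comp_id = "c"), blk@name)
    for (eid in entTab$id) {
      rows <- seqTab[seqTab$entity_id == eid, , drop = FALSE]
      three <- rows$comp_id[order(rows$num)]
      sequences[[eid]] <- list(three = three,
                               one = paste(compOneLetter(three), collapse = ""))
    }
  } else {
    ## reconstruct per entity (= per chain when no struct_asym) from residues
    for (aid in asymIds) {
      eid <- asymEntity[[aid]]
      sel <- atoms[atoms$asym_ref == aid, , drop = FALSE]
      len <- max(c(sel$seq_id, spheres$seq_end[spheres$asym_ref == aid], 0L))
      if (len == 0L) next
      three <- rep(NA_character_, len)
      if (nrow(sel)) three[sel$seq_id] <- sel$comp_id
      sequences[[eid]] <- list(three = three,
                               one = paste(compOneLetter(three), collapse = ""))
    }
  }

  ranges <- list()
  for (aid in asymIds) {
    b <- c(atoms$seq_id[atoms$asym_ref == aid],
           spheres$seq_begin[spheres$asym_ref == aid])
    e <- c(atoms$seq_id[atoms$asym_ref == aid],
           spheres$seq_end[spheres$asym_ref == aid])
    ranges[[aid]] <- mergeRanges(as.integer(b), as.integer(e))
  }

  new("DerivedFacts", n_models = as.integer(nModels), asym_ids = asymIds,
      sequences = sequences, has_atoms = hasAtoms, has_spheres = hasSpheres,
      modeled_ranges = ranges)
}
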