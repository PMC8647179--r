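## CSV/TSV restraint templates. The documented cross-link template matches
## what depositors fill out; ingestion is atomic (any malformed row rejects
## the whole file, which is then fixed and re-uploaded).

#' Documented restraint CSV template columns
#'
#' @param kind `"crosslink"` (with a linker column) or `"distance"`
#'   (generic distance restraints, no linker)
#' @return character vector of template column names
#' @export
crosslinkCsvColumns <- function(kind = c("crosslink", "distance")) {
  kind <- match.arg(kind)
  cols <- c("group_id", "entity_id_1", "seq_id_1", "comp_id_1", "atom_id_1",
            "entity_id_2", "seq_id_2", "comp_id_2", "atom_id_2", "linker",
            "threshold_A", "restraint_form", "conditionality", "dataset_id")
  if (kind == "distance") cols <- setdiff(cols, "linker")
  cols
}

sniffDelimiter <- function(text) {
  header <- strsplit(text, "\n", fixed = TRUE)[[1L]][[1L]]
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Parse a restraint CSV/TSV against an entry
#'
#' Each well-formed row becomes a cross-link restraint; each malformed row
#' yields a finding with its file line number (the header is line 1).
#' Component ids are cross-checked against the entity sequence at the given
#' residue position (a parent--child check). Ingestion is atomic: if any
#' row has an error, no restraints are returned. Asym units are resolved
#' automatically when the entity has exactly one chain.
#'
#' @param csvText CSV or TSV text matching the documented template
#' @param entry the [IhmEntry-class] the restraints belong to
#' @param kind `"crosslink"` or `"distance"`
#' @param idOffset restraint ids are numbered from `idOffset + 1`
#' @return `list(restraints=, findings=)`; `findings` has columns `line`,
#'   `message`
#' @export
parseRestraintCsv <- function(csvText, entry, kind = c("crosslink", "distance"),
                              idOffset = 0L) {
  kind <- match.arg(kind)
  expected <- crosslinkCsvColumns(kind)
  delim <- sniffDelimiter(csvText)
  df <- utils::read.delim(text = csvText, sep = delim, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  if (!setequal(names(df), expected))
    stop("unknown restraint CSV header; expected columns: ",
         paste(expected, collapse = ", "), call. = FALSE)
  findings <- list()
  note <- function(i, msg) findings[[length(findings) + 1L]] <<- data.frame(
    line = i + 1L, message = msg, stringsAsFactors = FALSE)

  asymOf <- function(eid) {
    hits <- entry@asyms$id[entry@asyms$entity_ref == eid]
    if (length(hits) == 1L) hits else NA_character_
  }
  rows <- list()
  for (i in seq_len(nrow(df))) {
    r <- as.list(df[i, ])
    rowOk <- TRUE
    bad <- function(msg) { note(i, msg); rowOk <<- FALSE }
    ends <- list()
    for (side in 1:2) {
      eid <- r[[paste0("entity_id_", side)]]
      seqTxt <- r[[paste0("seq_id_", side)]]
      comp <- r[[paste0("comp_id_", side)]]
      ent <- entityById(entry, eid)
      if (is.null(ent)) { bad(sprintf("entity_id_%d '%s' not in entry", side, eid)); next }
      if (!grepl("^[0-9]+$", seqTxt)) { bad(sprintf("seq_id_%d '%s' is not a positive integer", side, seqTxt)); next }
      seq <- as.integer(seqTxt)
      if (seq < 1L || seq > length(ent$sequence)) {
        bad(sprintf("seq_id_%d %d outside entity '%s' (length %d)", side, seq,
                    eid, length(ent$sequence)))
        next
      }
      if (toupper(comp) != toupper(ent$sequence[[seq]]))
        bad(sprintf("comp_id_%d '%s' disagrees with entity '%s' sequence at %d ('%s')",
                    side, comp, eid, seq, ent$sequence[[seq]]))
      ends[[side]] <- list(entity = eid, seq = seq,
                           atom = if (nzchar(r[[paste0("atom_id_", side)]]))
                             r[[paste0("atom_id_", side)]] else NA_character_)
    }
    thr <- suppressWarnings(as.numeric(r$threshold_A))
    if (is.na(thr) || thr <= 0) bad(sprintf("threshold_A '%s' must be > 0", r$threshold_A))
    if (!r$restraint_form %in% c("upper-bound", "lower-bound", "harmonic"))
      bad(sprintf("restraint_form '%s' invalid", r$restraint_form))
    if (!r$conditionality %in% c("any", "all"))
      bad(sprintf("conditionality '%s' invalid", r$conditionality))
    if (!nzchar(r$group_id)) bad("group_id must be non-empty")
    if (!rowOk) next
    byAtom <- !is.na(ends[[1]]$atom) && !is.na(ends[[2]]$atom)
    rows[[length(rows) + 1L]] <- data.frame(
      id = as.character(idOffset + length(rows) + 1L), group_id = r$group_id,
      entity_ref_1 = ends[[1]]$entity, asym_ref_1 = asymOf(ends[[1]]$entity),
      seq_id_1 = ends[[1]]$seq, atom_name_1 = ends[[1]]$atom,
      entity_ref_2 = ends[[2]]$entity, asym_ref_2 = asymOf(ends[[2]]$entity),
      seq_id_2 = ends[[2]]$seq, atom_name_2 = ends[[2]]$atom,
      linker = if (kind == "crosslink") r$linker else NA_character_,
      threshold = thr, restraint_form = r$restraint_form,
      granularity = if (byAtom) "by-atom" else "by-residue",
      conditionality = r$conditionality, dataset_ref = r$dataset_id,
      stringsAsFactors = FALSE)
  }
  findings <- if (length(findings)) do.call(rbind, findings) else
    data.frame(line = integer(0), message = character(0), stringsAsFactors = FALSE)
  restraints <- if (nrow(findings) == 0L && length(rows))
    coerceTyped(do.call(rbind, rows), .entrySchemas$crosslinks, "crosslinks")
  else emptyTyped(.entrySchemas$crosslinks)
  list(restraints = restraints, findings = findings)
}

#' Ingest a restraint CSV into a submission
#'
#' Wraps [parseRestraintCsv()] for the harvesting workflow: the file is also
#' stored (with its hash) under the `restraint-csv` role, and accepted
#' restraints are appended to the submission. Atomic: a file with any
#' malformed row stores nothing.
#'
#' @param sub a [Submission-class] in status `ANNOT` with a processed model
#' @param kind `"crosslink"` or `"distance"`
#' @param csvText the CSV/TSV text
#' @param name stored-file name
#' @return `list(sub=, restraints=, findings=)`
#' @export
ingestRestraintCsv <- function(sub, kind, csvText, name = "restraints.csv") {
  if (sub@status != "ANNOT")
    stop("invalid state: restraints can be ingested only in status ANNOT (now ",
         sub@status, ")", call. = FALSE)
  if (is.null(sub@entry))
    stop("invalid state: model file has not been processed", call. = FALSE)
  res <- parseRestraintCsv(csvText, sub@entry, kind,
                           idOffset = nrow(sub@restraints))
  st <- storeFile(sub, "restraint-csv", name, csvText)
  sub <- st$sub
  if (nrow(res$findings) == 0L)
    sub@restraints <- rbind(sub@restraints, res$restraints)
  list(sub = sub, restraints = res$restraints, findings = res$findings)
}
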