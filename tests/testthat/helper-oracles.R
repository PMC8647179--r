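## Independent oracles used across the suite. Each deliberately uses a
## different algorithmic structure from the implementation it checks.

## --- character-level STAR tokenizer (state machine), oracle for the
## line/regex-based parser tokenizer ------------------------------------------
oracleTokenize <- function(text) {
  text <- gsub("\r\n?", "\n", text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  texts <- character(0); quoted <- logical(0)
  push <- function(t, q) {
    texts[[length(texts) + 1L]] <<- t
    quoted[[length(quoted) + 1L]] <<- q
  }
  i <- 1L
  atLineStart <- TRUE
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "\n") { atLineStart <- TRUE; i <- i + 1L; next }
    if (ch == " " || ch == "\t") { atLineStart <- FALSE; i <- i + 1L; next }
    if (ch == ";" && atLineStart) {
      j <- i + 1L
      buf <- character(0)
      repeat {
        if (j > n) stop("oracle: unterminated fence")
        if (chars[[j]] == "\n" && j < n && chars[[j + 1L]] == ";") break
        buf <- c(buf, chars[[j]])
        j <- j + 1L
      }
      push(paste(buf, collapse = ""), TRUE)
      i <- j + 2L
      atLineStart <- FALSE
      next
    }
    atLineStart <- FALSE
    if (ch == "#") {
      while (i <= n && chars[[i]] != "\n") i <- i + 1L
      next
    }
    if (ch == "'" || ch == "\"") {
      j <- i + 1L
      buf <- character(0)
      repeat {
        if (j > n) stop("oracle: unterminated quote")
        if (chars[[j]] == ch &&
            (j == n || chars[[j + 1L]] %in% c(" ", "\t", "\n"))) break
        buf <- c(buf, chars[[j]])
        j <- j + 1L
      }
      push(paste(buf, collapse = ""), TRUE)
      i <- j + 1L
      next
    }
    j <- i
    buf <- character(0)
    while (j <= n && !chars[[j]] %in% c(" ", "\t", "\n")) {
      buf <- c(buf, chars[[j]])
      j <- j + 1L
    }
    push(paste(buf, collapse = ""), FALSE)
    i <- j
  }
  list(text = texts, quoted = quoted)
}

## --- exhaustive semi-global alignment oracle --------------------------------
## Enumerates every distinct alignment as an order-preserving mapping of k
## model positions onto k reference positions (k = 0..min(m, n)); terminal
## reference overhangs are free, internal unmapped positions cost one gap
## each. Returns the optimal score and the set of identity percentages
## achieved by optimal alignments.
bruteForceAlign <- function(model, ref, scoring = list(match = 1, mismatch = -1,
                                                       gap = -2)) {
  a <- strsplit(toupper(model), "")[[1]]
  b <- strsplit(toupper(ref), "")[[1]]
  m <- length(a); n <- length(b)
  best <- m * scoring$gap           # k = 0: everything gapped
  ids <- 0
  consider <- function(score, identity) {
    if (score > best + 1e-9) { best <<- score; ids <<- identity }
    else if (abs(score - best) < 1e-9) ids <<- unique(c(ids, identity))
  }
  for (k in seq_len(min(m, n))) {
    ms <- if (k == m) matrix(seq_len(m), ncol = 1) else utils::combn(m, k)
    rs <- if (k == n) matrix(seq_len(n), ncol = 1) else utils::combn(n, k)
    span <- rs[k, , drop = TRUE] - rs[1, , drop = TRUE] + 1L
    for (ci in seq_len(ncol(ms))) {
      sel <- ms[, ci]
      matches <- colSums(matrix(b[rs], nrow = k) == a[sel])
      gaps <- (m - k) + (span - k)
      score <- matches * scoring$match + (k - matches) * scoring$mismatch +
        gaps * scoring$gap
      identity <- 100 * matches / (matches + (k - matches) + gaps)
      for (q in seq_along(score)) consider(score[[q]], identity[[q]])
    }
  }
  list(score = best, identities = ids)
}

## --- brute-force cross-link satisfaction scan -------------------------------
## Plain loop over every restraint, member pair and model; nested-list
## coordinate tables instead of the implementation's hashed index.
bruteForceSatisfaction <- function(entry, rule = "any-model") {
  at <- entry@atoms; sp <- entry@spheres
  ca <- list(); anyAtom <- list(); bead <- list()
  for (i in seq_len(nrow(at))) {
    keyMA <- paste(at$model_ref[[i]], at$asym_ref[[i]])
    anyAtom[[paste(keyMA, at$seq_id[[i]], at$atom_name[[i]])]] <-
      c(at$x[[i]], at$y[[i]], at$z[[i]])
    if (at$atom_name[[i]] == "CA")
      ca[[paste(keyMA, at$seq_id[[i]])]] <- c(at$x[[i]], at$y[[i]], at$z[[i]])
  }
  for (i in seq_len(nrow(sp)))
    for (s in seq(sp$seq_begin[[i]], sp$seq_end[[i]]))
      bead[[paste(sp$model_ref[[i]], sp$asym_ref[[i]], s)]] <-
        c(sp$x[[i]], sp$y[[i]], sp$z[[i]])
  asymsOf <- split(entry@asyms$id, entry@asyms$entity_ref)
  pointOf <- function(model, entityRef, asym, seq, atom, gran) {
    cands <- if (is.na(asym)) asymsOf[[entityRef]] else asym
    out <- list()
    for (aid in cands) {
      p <- NULL
      if (gran == "by-atom" && !is.na(atom))
        p <- anyAtom[[paste(model, aid, seq, atom)]]
      if (is.null(p)) p <- ca[[paste(model, aid, seq)]]
      if (is.null(p)) p <- bead[[paste(model, aid, seq)]]
      if (!is.null(p)) out[[length(out) + 1L]] <- p
    }
    out
  }
  xl <- entry@crosslinks
  groups <- unique(xl$group_id)
  nSat <- 0L; nViol <- 0L; excluded <- character(0); notEval <- character(0)
  for (g in groups) {
    rows <- which(xl$group_id == g & xl$restraint_form == "upper-bound")
    if (!length(rows)) { notEval <- c(notEval, g); next }
    cond <- xl$conditionality[[rows[[1]]]]
    thr <- xl$threshold[[rows[[1]]]]
    perModel <- logical(0)
    skip <- FALSE
    for (mid in entry@models$id) {
      ds <- numeric(0)
      for (r in rows) {
        p1 <- pointOf(mid, xl$entity_ref_1[[r]], xl$asym_ref_1[[r]],
                      xl$seq_id_1[[r]], xl$atom_name_1[[r]], xl$granularity[[r]])
        p2 <- pointOf(mid, xl$entity_ref_2[[r]], xl$asym_ref_2[[r]],
                      xl$seq_id_2[[r]], xl$atom_name_2[[r]], xl$granularity[[r]])
        if (!length(p1) || !length(p2)) { skip <- TRUE; break }
        dmin <- Inf
        for (u in p1) for (v in p2) dmin <- min(dmin, sqrt(sum((u - v)^2)))
        ds <- c(ds, dmin)
      }
      if (skip) break
      gd <- if (cond == "any") min(ds) else max(ds)
      perModel <- c(perModel, gd <= thr)
    }
    if (skip) { excluded <- c(excluded, g); next }
    ok <- if (rule == "any-model") any(perModel) else all(perModel)
    if (ok) nSat <- nSat + 1L else nViol <- nViol + 1L
  }
  list(n_satisfied = nSat, n_violated = nViol, excluded = excluded,
       not_evaluated = notEval)
}

## --- tiny hand-built entries for cross-link unit cases ----------------------
## Atomic chain of `len` CA atoms placed on the x axis at the given
## x-coordinates, one model per row of `xs`.
tinyAtomicEntry <- function(xs, crosslinks, len = ncol(xs)) {
  stopifnot(len >= ncol(xs))  # residues beyond ncol(xs) have no coordinates
  seqs <- rep("ALA", len)
  models <- paste0("m", seq_len(nrow(xs)))
  atoms <- do.call(rbind, lapply(seq_len(nrow(xs)), function(m)
    data.frame(model_ref = models[[m]], asym_ref = "A",
               seq_id = seq_len(ncol(xs)),
               comp_id = "ALA", atom_name = "CA", element = "C",
               x = xs[m, ], y = 0, z = 0, stringsAsFactors = FALSE)))
  ihmEntry(
    id = "TINY", title = "tiny crosslink case",
    entities = list(list(id = "e1", kind = "polymer", polymer_type = "protein",
                         sequence = seqs, description = "tiny chain")),
    asyms = data.frame(id = "A", entity_ref = "e1"),
    assemblies = data.frame(id = "asm1", asym_ref = "A", seq_begin = 1L,
                            seq_end = len),
    representations = data.frame(id = "rep1", asym_ref = "A", seq_begin = 1L,
                                 seq_end = len, mode = "atomic",
                                 granularity = "by-residue", is_rigid = FALSE,
                                 starting_model_ref = NA),
    models = data.frame(id = models, assembly_ref = "asm1",
                        representation_ref = "rep1", protocol_ref = NA),
    atoms = atoms,
    datasets = data.frame(id = "ds1", data_type = "CX-MS",
                          db_name = "ProteomeXchange", accession = "PXD1",
                          doi = NA, file_path = NA),
    crosslinks = crosslinks)
}

tinyXlRow <- function(id, group, seq1, seq2, threshold, cond = "any",
                      form = "upper-bound") {
  data.frame(id = id, group_id = group, entity_ref_1 = "e1", asym_ref_1 = "A",
             seq_id_1 = seq1, atom_name_1 = NA, entity_ref_2 = "e1",
             asym_ref_2 = "A", seq_id_2 = seq2, atom_name_2 = NA,
             linker = "DSS", threshold = threshold, restraint_form = form,
             granularity = "by-residue", conditionality = cond,
             dataset_ref = "ds1", stringsAsFactors = FALSE)
}
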