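miniDict <- loadDictionary(file = system.file("extdata", "mini_ihm_dict.cif",
                                              package = "ihmforge"))

preparedSubmission <- function(seed = 50, ...) {
  fx <- generateEntry(toyConfig(seed = seed, ...))
  upload <- stripToModelUpload(fx$entry)
  sub <- createSubmission("dep1")
  sub <- storeFile(sub, "model", "model.cif",
                   writeCif(entryToDocument(upload)))$sub
  list(sub = processModelUpload(sub), fx = fx)
}

annotatedSubmission <- function(seed = 50, ...) {
  p <- preparedSubmission(seed, ...)
  sub <- p$sub
  sub <- recordMetadata(sub, "authors",
                        data.frame(ordinal = 1:2,
                                   name = c("Doe, Jane", "Roe, Richard")),
                        miniDict)$sub
  sub <- recordMetadata(sub, "citations",
                        data.frame(id = "cit1", title = "A structure",
                                   journal = "J. Test", doi = "10.1/x",
                                   pmid = NA,
                                   authors = "Doe, Jane; Roe, Richard"),
                        miniDict)$sub
  csv <- generateCrosslinkCsv(p$fx$entry)
  sub <- ingestRestraintCsv(sub, "crosslink", csv)$sub
  list(sub = sub, fx = p$fx)
}

test_that("submissions are created in DRAFT with distinct ids", {
  a <- createSubmission("user1")
  b <- createSubmission("user1")
  expect_equal(submissionStatus(a), "DRAFT")
  expect_length(a@files, 0L)
  expect_equal(nrow(statusHistory(a)), 1L)
  expect_equal(statusHistory(a)$from, "NONE")
  expect_false(identical(a@entryId, b@entryId))
  expect_error(createSubmission(""), "non-empty")
})

test_that("depositors see only their own submissions, curators see all", {
  sub <- createSubmission("user1")
  expect_true(submissionVisible(sub, "user1", "depositor"))
  expect_false(submissionVisible(sub, "user2", "depositor"))
  expect_true(submissionVisible(sub, "user2", "curator"))
  expect_true(submissionVisible(sub, "user2", "admin"))
})

test_that("stored files are content-addressed and versioned", {
  sub <- createSubmission("u")
  ## digest of zero bytes, computed with an independent implementation
  ## (openssl::sha256 on raw(0)) and frozen here
  emptyHash <- "e3b0c44298fc1c149afbf4c8996fb92427ae41e4649b934ca495991b7852b855"
  st <- storeFile(sub, "model", "empty.cif", raw(0))
  expect_equal(st$file$content_hash, emptyHash)
  if (requireNamespace("openssl", quietly = TRUE))
    expect_equal(as.character(openssl::sha256(raw(0))), emptyHash,
                 ignore_attr = TRUE)

  st2 <- storeFile(st$sub, "model", "empty.cif", raw(0))
  expect_equal(st2$file$version, 2L)
  expect_equal(st2$file$content_hash, st$file$content_hash)
  ## both versions retrievable
  expect_equal(readStoredFile(st2$sub, "empty.cif", "model", 1)$version, 1L)
  expect_equal(readStoredFile(st2$sub, "empty.cif", "model")$version, 2L)
})

test_that("any single-byte corruption of a stored file is detected", {
  sub <- storeFile(createSubmission("u"), "model", "f.cif", "data_x\n_a.b 1\n")$sub
  for (pos in c(1L, 5L, 14L)) {
    tampered <- sub
    content <- tampered@files[[1]]$content
    content[pos] <- xor(content[pos], as.raw(1L))
    tampered@files[[1]]$content <- content
    expect_error(readStoredFile(tampered, "f.cif", "model"),
                 "integrity check failed")
  }
})

test_that("model processing derives facts or lands in ERROR with the cause", {
  p <- preparedSubmission(51, n_models = 3)
  expect_equal(submissionStatus(p$sub), "ANNOT")
  expect_equal(p$sub@derivedFacts@n_models, 3L)
  expect_equal(statusHistory(p$sub)$to, c("DRAFT", "PROC", "ANNOT"))

  bad <- createSubmission("u")
  bad <- storeFile(bad, "model", "broken.cif", "data_x\n_a.b 'oops\n")$sub
  bad <- processModelUpload(bad)
  expect_equal(submissionStatus(bad), "ERROR")
  lastNote <- tail(statusHistory(bad)$note, 1)
  expect_match(lastNote, "line 2")  # error communicated back with its line

  ## fixed file re-uploaded after ERROR goes PROC then ANNOT
  fixedEntry <- stripToModelUpload(generateEntry(toyConfig(seed = 52))$entry)
  bad <- storeFile(bad, "model", "broken.cif",
                   writeCif(entryToDocument(fixedEntry)))$sub
  fixed <- processModelUpload(bad)
  expect_equal(submissionStatus(fixed), "ANNOT")
  expect_equal(tail(statusHistory(fixed)$to, 2), c("PROC", "ANNOT"))
  expect_error(processModelUpload(createSubmission("u")), "no model file")
})

test_that("metadata records are validated, versioned and snapshotted", {
  sub <- preparedSubmission(53)$sub
  r1 <- recordMetadata(sub, "citations",
                       data.frame(id = "c1", title = "Original title",
                                  journal = "J. One", doi = NA, pmid = NA),
                       miniDict)
  expect_equal(r1$record$version, 1L)
  sub <- r1$sub

  ## invalid vocabulary rejected, store unchanged
  r2 <- recordMetadata(sub, "dataset_refs",
                       data.frame(id = "d1", data_type = "FOO"), miniDict)
  expect_null(r2$record)
  expect_true(any(r2$findings$kind == "ENUM_VIOLATION"))
  expect_error(getSnapshot(r2$sub, paste0(sub@entryId, ":dataset_refs")),
               "not found")

  ## editing makes version 2; version 1 stays intact
  r3 <- recordMetadata(sub, "citations",
                       data.frame(id = "c1", title = "Edited title",
                                  journal = "J. One", doi = NA, pmid = NA),
                       miniDict)
  expect_equal(r3$record$version, 2L)
  recId <- r3$record$record_id
  expect_equal(getSnapshot(r3$sub, recId, 1)$title, "Original title")
  expect_equal(getSnapshot(r3$sub, recId, 2)$title, "Edited title")
  expect_equal(getSnapshot(r3$sub, recId)$title, "Edited title")
  expect_error(getSnapshot(r3$sub, recId, 3), "not found")
  expect_error(recordMetadata(sub, "nonsense", data.frame(x = 1), miniDict),
               "unknown metadata section")
  expect_error(recordMetadata(createSubmission("u"), "citations",
                              data.frame(), miniDict),
               "only in status ANNOT")
})

test_that("restraint CSV ingestion is validated, atomic and parent-checked", {
  p <- preparedSubmission(54)
  sub <- p$sub
  full <- p$fx$entry
  csv <- generateCrosslinkCsv(full)
  expect_equal(strsplit(csv, "\n")[[1]][1],
               paste(crosslinkCsvColumns(), collapse = ","))

  ri <- ingestRestraintCsv(sub, "crosslink", csv)
  expect_equal(nrow(ri$findings), 0L)
  expect_equal(nrow(ri$restraints), nrow(full@crosslinks))
  ## ingestion reproduces the generator's restraint set exactly
  expect_true(isTRUE(all.equal(ri$restraints, full@crosslinks,
                               check.attributes = FALSE)))

  ## negative threshold: finding with its line, nothing stored
  lines <- strsplit(csv, "\n")[[1]]
  parts <- strsplit(lines[3], ",")[[1]]
  parts[which(crosslinkCsvColumns() == "threshold_A")] <- "-5"
  lines[3] <- paste(parts, collapse = ",")
  bad <- ingestRestraintCsv(sub, "crosslink", paste(lines, collapse = "\n"))
  expect_equal(bad$findings$line, 3L)
  expect_match(bad$findings$message, "threshold_A")
  expect_equal(nrow(bad$restraints), 0L)
  expect_equal(nrow(bad$sub@restraints), 0L)

  ## component disagreeing with the entity sequence is a parent mismatch
  parts <- strsplit(lines[2], ",")[[1]]
  parts[which(crosslinkCsvColumns() == "comp_id_1")] <- "ZZZ"
  lines2 <- strsplit(csv, "\n")[[1]]
  lines2[2] <- paste(parts, collapse = ",")
  mism <- ingestRestraintCsv(sub, "crosslink", paste(lines2, collapse = "\n"))
  expect_match(mism$findings$message[1], "disagrees with entity")

  expect_error(ingestRestraintCsv(sub, "crosslink", "a,b,c\n1,2,3\n"),
               "expected columns")

  ## TSV accepted by delimiter sniffing
  tsv <- gsub(",", "\t", csv, fixed = TRUE)
  expect_equal(nrow(ingestRestraintCsv(sub, "crosslink", tsv)$restraints),
               nrow(full@crosslinks))
})

test_that("submission merges all parts into a compliant aggregate", {
  ann <- annotatedSubmission(55)
  sub <- submitSubmission(ann$sub, miniDict)
  expect_equal(submissionStatus(sub), "SUBMIT")
  expect_true(isCompliant(sub@complianceReport))
  agg <- Filter(function(f) f$role == "aggregate", sub@files)
  expect_length(agg, 1L)
  ## the aggregate carries the metadata and the restraints
  entry <- buildAggregateEntry(sub)
  expect_equal(entry@authors, c("Doe, Jane", "Roe, Richard"))
  expect_equal(nrow(entry@crosslinks), nrow(ann$fx$entry@crosslinks))
  expect_equal(nrow(entry@citationAuthors), 2L)
})

test_that("submission gates on mandatory metadata sections", {
  p <- preparedSubmission(56)
  sub <- recordMetadata(p$sub, "authors",
                        data.frame(ordinal = 1, name = "Doe, Jane"),
                        miniDict)$sub
  expect_error(submitSubmission(sub, miniDict),
               "mandatory metadata section 'citations'")
  expect_error(submitSubmission(createSubmission("u"), miniDict),
               "only from status ANNOT")
})

test_that("a complete compliant file can bypass the metadata steps", {
  full <- generateEntry(toyConfig(seed = 57))$entry  # already has everything
  sub <- createSubmission("power-user")
  sub <- storeFile(sub, "model", "complete.cif",
                   writeCif(entryToDocument(full)))$sub
  sub <- processModelUpload(sub)
  sub <- submitSubmission(sub, miniDict)  # no metadata or CSV steps
  expect_equal(submissionStatus(sub), "SUBMIT")
  expect_true(isCompliant(sub@complianceReport))
})

test_that("every unlisted (status, action) pair is rejected", {
  tab <- workflowTransitions()
  actions <- unique(tab$action)
  for (status in ihmforge:::WORKFLOW_STATUSES) {
    sub <- createSubmission("u")
    sub@status <- status
    sub@statusHistory <- data.frame(from = "NONE", to = status, actor = "t",
                                    note = "", at = "t")
    for (action in actions) {
      allowed <- any(tab$action == action & tab$from == status)
      if (allowed) {
        moved <- ihmforge:::applyTransition(sub, action, "test")
        expect_equal(submissionStatus(moved),
                     tab$to[tab$action == action & tab$from == status])
      } else {
        expect_error(ihmforge:::applyTransition(sub, action, "test"),
                     "invalid transition", info = paste(status, action))
      }
    }
  }
})

test_that("no workflow path skips processing on the way to SUBMIT", {
  tab <- workflowTransitions()
  ## reachability avoiding PROC, by exhaustive graph search
  reachAvoiding <- function(from, to, avoid) {
    seen <- from
    repeat {
      nxt <- unique(tab$to[tab$from %in% seen & !tab$to %in% c(avoid, seen)])
      if (!length(nxt)) return(to %in% seen)
      seen <- c(seen, nxt)
    }
  }
  expect_false(reachAvoiding("DRAFT", "SUBMIT", avoid = "PROC"))
  expect_false(reachAvoiding("ERROR", "SUBMIT", avoid = "PROC"))
  expect_true(reachAvoiding("DRAFT", "SUBMIT", avoid = character(0)))
})
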