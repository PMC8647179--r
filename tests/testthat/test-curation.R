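test_that("alignment handles identity, substitution and embedding", {
  r <- alignToReference("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(r@score, 10)
  expect_equal(r@identity_percent, 100)
  expect_equal(c(r@model_begin, r@model_end, r@ref_begin, r@ref_end),
               c(1L, 10L, 1L, 10L))

  r <- alignToReference("ACDEFGHIKL", "ACDEWGHIKL")  # position 5 substituted
  expect_equal(r@identity_percent, 90)
  expect_equal(r@n_matches, 9L)
  expect_equal(r@n_mismatches, 1L)

  ## expected values frozen from the exhaustive brute-force oracle:
  ## bruteForceAlign("CDE", "ABCDEFG") gives score 3, identity 100
  r <- alignToReference("CDE", "ABCDEFG")
  expect_equal(r@score, 3)
  expect_equal(r@identity_percent, 100)
  expect_equal(c(r@ref_begin, r@ref_end), c(3L, 5L))
  orc <- bruteForceAlign("CDE", "ABCDEFG")
  expect_equal(orc$score, 3)
  expect_true(100 %in% orc$identities)

  expect_error(alignToReference("", "AC"), "non-empty")
  expect_error(alignToReference("A C", "AC"), "A-Z")
})

test_that("alignment matches the exhaustive oracle on random small pairs", {
  set.seed(101)
  alph <- c("A", "C", "D", "E", "G")
  for (i in 1:40) {
    m <- paste(sample(alph, sample(1:6, 1), replace = TRUE), collapse = "")
    r <- paste(sample(alph, sample(1:12, 1), replace = TRUE), collapse = "")
    res <- alignToReference(m, r)
    orc <- bruteForceAlign(m, r)
    expect_equal(res@score, orc$score, info = paste(m, r))
    expect_true(any(abs(orc$identities - res@identity_percent) < 1e-9),
                info = paste(m, r))
  }
})

test_that("alignment scores match an independent DP up to length 50", {
  sm <- matrix(-1, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(sm) <- 1
  set.seed(102)
  for (i in 1:25) {
    m <- paste(sample(LETTERS[1:20], sample(3:50, 1), replace = TRUE), collapse = "")
    r <- paste(sample(LETTERS[1:20], sample(3:50, 1), replace = TRUE), collapse = "")
    pa <- Biostrings::pairwiseAlignment(m, r, type = "global-local",
                                        substitutionMatrix = sm,
                                        gapOpening = 0, gapExtension = 2)
    expect_equal(alignToReference(m, r)@score, Biostrings::score(pa),
                 info = paste(m, r))
  }
})

test_that("reference annotation honors the identity threshold", {
  entry <- generateEntry(toyConfig(seed = 40, n_entities = 2))$entry
  seq1 <- paste(compOneLetter(entry@entities[[1]]$sequence), collapse = "")

  res <- alignToReference(seq1, seq1)
  ann <- annotateReference(entry, "e1", "UniProt", "P12345", res)
  expect_equal(nrow(ann$entry@seqReferences), 1L)
  expect_equal(ann$entry@seqReferences$accession, "P12345")
  expect_equal(ann$entry@seqReferences$identity_percent, 100)
  expect_equal(nrow(ann$findings), 0L)

  ## a weak alignment is refused and the entry left untouched
  weak <- res
  weak@identity_percent <- 80
  ann2 <- annotateReference(entry, "e1", "UniProt", "P99999", weak)
  expect_equal(nrow(ann2$entry@seqReferences), 0L)
  expect_equal(ann2$findings$kind, "SEQUENCE_MISMATCH")

  ## two entities annotated independently
  seq2 <- paste(compOneLetter(entry@entities[[2]]$sequence), collapse = "")
  step1 <- annotateReference(entry, "e1", "UniProt", "P1", alignToReference(seq1, seq1))
  step2 <- annotateReference(step1$entry, "e2", "INSDC", "X1",
                             alignToReference(seq2, seq2))
  expect_equal(nrow(step2$entry@seqReferences), 2L)
  expect_error(annotateReference(entry, "nope", "UniProt", "P1", res), "no entity")
})

ligandEntry <- function(comp, desc) {
  fx <- generateEntry(toyConfig(seed = 41))$entry
  fx@entities <- c(fx@entities,
                   list(list(id = "lig1", kind = "nonpolymer",
                             polymer_type = NA_character_, sequence = comp,
                             description = desc)))
  fx
}

test_that("component nomenclature is checked against the mini component set", {
  ccd <- miniChemCompDictionary()
  expect_equal(nrow(checkChemComp(ligandEntry("ATP", "adenosine-5'-triphosphate"), ccd)), 0L)

  f <- checkChemComp(ligandEntry("XXQ", "mystery ligand"), ccd)
  expect_equal(f$kind, "UNKNOWN_COMP")
  expect_equal(f$comp_id, "XXQ")

  f <- checkChemComp(ligandEntry("ATP", "adenosine monophosphate"), ccd)
  expect_equal(f$kind, "NAME_MISMATCH")

  ## additivity: findings for a union of components are the union of findings
  both <- ligandEntry("XXQ", "mystery ligand")
  both@entities <- c(both@entities,
                     list(list(id = "lig2", kind = "nonpolymer",
                               polymer_type = NA_character_, sequence = "ATP",
                               description = "adenosine monophosphate")))
  f <- checkChemComp(both, ccd)
  expect_setequal(f$kind, c("UNKNOWN_COMP", "NAME_MISMATCH"))
})

test_that("accession codes are sequential, gap-free and idempotent", {
  reg <- withr::local_tempfile(fileext = ".json")
  newAccessionRegistry(reg)
  expect_equal(issueAccession(reg, "entryA")$code, "PDBDEV_00000001")
  expect_equal(issueAccession(reg, "entryB")$code, "PDBDEV_00000002")
  ## idempotent per entry: no new number consumed
  expect_equal(issueAccession(reg, "entryA")$code, "PDBDEV_00000001")
  expect_equal(issueAccession(reg, "entryC")$code, "PDBDEV_00000003")
  tab <- listAccessions(reg)
  expect_equal(nrow(tab), 3L)
  nums <- as.integer(sub("PDBDEV_", "", tab$code))
  expect_equal(nums, 1:3)  # strictly increasing, never reused, gap-free
  expect_true(all(grepl(ihmforge:::ACCESSION_PATTERN, tab$code)))
  expect_error(issueAccession(file.path(tempdir(), "absent", "r.json"), "x"),
               "does not exist")
})

test_that("release follows depositor instructions and the hold rule", {
  submitted <- function() {
    sub <- createSubmission("dep1")
    sub@status <- "SUBMIT"   # jump a curated submission into place
    sub@statusHistory <- rbind(sub@statusHistory,
                               data.frame(from = "DRAFT", to = "SUBMIT",
                                          actor = "depositor", note = "",
                                          at = "t"))
    sub
  }
  rel <- releaseEntry(submitted(), "immediate")
  expect_equal(submissionStatus(rel), "REL")

  held <- releaseEntry(submitted(), "on_publication", publicationReleased = FALSE)
  expect_equal(submissionStatus(held), "HOLD")
  expect_equal(submissionStatus(releaseEntry(held, "on_publication", FALSE)), "HOLD")
  expect_equal(submissionStatus(releaseEntry(held, "on_publication", TRUE)), "REL")

  expect_error(releaseEntry(createSubmission("dep1"), "immediate"),
               "invalid transition")
})

test_that("reference sequences load from FASTA and plain text", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|TEST first", "ACDEF", "GHIKL", ">r2", "MNPQ"), fa)
  refs <- referenceFromFasta(fa)
  expect_equal(unname(refs[1]), "ACDEFGHIKL")
  expect_length(refs, 2L)

  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("acdef", "ghikl"), txt)
  expect_equal(unname(referenceFromFasta(txt)), "ACDEFGHIKL")
})
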