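fixtureEntry <- function(seed = 1, ...) generateEntry(toyConfig(seed = seed, ...))$entry

test_that("referential integrity reports exactly the dangling references", {
  entry <- fixtureEntry(1)
  expect_equal(nrow(validateReferentialIntegrity(entry)), 0L)

  broken <- entry
  broken@models$assembly_ref[[1]] <- "A9"
  f <- validateReferentialIntegrity(broken)
  expect_equal(nrow(f), 1L)
  expect_match(f$object, "model 'm1'")
  expect_equal(f$field, "assembly_ref")
  expect_equal(f$target, "A9")

  broken@ensembles$group_ref[[1]] <- "g99"
  broken@crosslinks$dataset_ref[[1]] <- "nope"
  expect_equal(nrow(validateReferentialIntegrity(broken)), 3L)
})

test_that("entries survive serialization to a document and back", {
  for (seed in c(2, 3)) {
    entry <- generateEntry(randomToyConfig(seed))$entry
    doc <- entryToDocument(entry)
    expect_length(doc@blocks, 1L)
    expect_equal(doc@blocks[[1]]@name, entry@id)
    back <- entryFromDocument(parseCif(writeCif(doc)))
    eq <- entriesEqual(entry, back)
    expect_true(isTRUE(eq), info = attr(eq, "difference"))
  }
})

test_that("serialization is deterministic and count-preserving", {
  entry <- fixtureEntry(4, n_states = 2)
  t1 <- writeCif(entryToDocument(entry))
  t2 <- writeCif(entryToDocument(entry))
  expect_identical(t1, t2)
  doc <- entryToDocument(entry)
  expect_equal(categoryRowCount(getCategory(doc@blocks[[1]], "state")), 2L)
})

test_that("a minimal entry emits no spurious categories", {
  entry <- ihmEntry(
    id = "MIN", title = "minimal",
    entities = list(list(id = "e1", kind = "polymer", polymer_type = "protein",
                         sequence = c("ALA", "GLY"), description = "tiny")),
    asyms = data.frame(id = "A", entity_ref = "e1"),
    assemblies = data.frame(id = "asm1", asym_ref = "A", seq_begin = 1L, seq_end = 2L),
    representations = data.frame(id = "r1", asym_ref = "A", seq_begin = 1L,
                                 seq_end = 2L, mode = "atomic",
                                 granularity = "by-residue", is_rigid = FALSE,
                                 starting_model_ref = NA),
    models = data.frame(id = "m1", assembly_ref = "asm1",
                        representation_ref = "r1", protocol_ref = NA),
    atoms = data.frame(model_ref = "m1", asym_ref = "A", seq_id = 1L,
                       comp_id = "ALA", atom_name = "CA", element = "C",
                       x = 0, y = 0, z = 0))
  doc <- entryToDocument(entry)
  nms <- categoryNames(doc@blocks[[1]])
  expect_false(any(c("crosslink_restraint", "state", "ensemble") %in% nms))
  expect_true(all(c("entry", "entity", "entity_seq", "struct_asym",
                    "atom_site") %in% nms))
})

test_that("unknown categories pass through a read/write cycle opaquely", {
  entry <- fixtureEntry(5)
  text <- writeCif(entryToDocument(entry))
  text <- paste0(text, "_custom.x special\n_custom.y 2\n")
  back <- entryFromDocument(parseCif(text))
  expect_length(back@extras, 1L)
  again <- writeCif(entryToDocument(back))
  expect_match(again, "_custom.x", fixed = TRUE)
  expect_match(again, "special", fixed = TRUE)
})

test_that("structural requirements and malformed cells raise named errors", {
  expect_error(entryFromDocument(parseCif("data_x\n_entity.id e1\n")),
               "no models found")
  expect_error(entryFromDocument(parseCif("data_x\n_atom_site.model_id m1\n")),
               "missing required category 'entity'")
  entry <- fixtureEntry(6)
  doc <- parseCif(writeCif(entryToDocument(entry)))
  cat <- getCategory(doc@blocks[[1]], "atom_site")
  cat <- setCifCell(cat, 1, "cartn_x", "NaNope")
  doc@blocks[[1]]@categories[["atom_site"]] <- cat
  expect_error(entryFromDocument(doc),
               "malformed numeric cell .* category 'atom_site', item 'cartn_x', row 1")
  expect_error(entryFromDocument(cifDocument(list(cifBlock("a"), cifBlock("b")))),
               "exactly one data block")
})

test_that("derived facts recover generator ground truth", {
  fx <- generateEntry(toyConfig(seed = 7, n_models = 3, chain_length = 100))
  facts <- deriveEntryFacts(entryToDocument(fx$entry))
  expect_equal(facts@n_models, 3L)
  expect_equal(facts@asym_ids, "A")
  expect_equal(facts@sequences$e1$three, fx$truth$sequences_three$e1)
  expect_equal(facts@sequences$e1$one, unname(fx$truth$sequences_one["e1"]))
  expect_equal(facts@modeled_ranges$A,
               matrix(c(1L, 100L), 1, 2, dimnames = list(NULL, c("begin", "end"))))
  expect_true(facts@has_atoms)
  expect_true(facts@has_spheres)
})

test_that("derived-fact flags follow the representation present", {
  atomsOnly <- generateEntry(toyConfig(seed = 8, atomic_fraction = 1,
                                       n_crosslinks_satisfied = 2,
                                       n_crosslinks_violated = 1))$entry
  facts <- deriveEntryFacts(entryToDocument(atomsOnly))
  expect_true(facts@has_atoms)
  expect_false(facts@has_spheres)

  spheresOnly <- generateEntry(toyConfig(seed = 9, atomic_fraction = 0,
                                         n_crosslinks_satisfied = 2,
                                         n_crosslinks_violated = 1))$entry
  facts <- deriveEntryFacts(entryToDocument(spheresOnly))
  expect_false(facts@has_atoms)
  expect_true(facts@has_spheres)
})

test_that("coordinates referencing undeclared chains are an error", {
  entry <- fixtureEntry(10)
  doc <- entryToDocument(entry)
  cat <- getCategory(doc@blocks[[1]], "atom_site")
  cat <- setCifCell(cat, 2, "asym_id", "ZZ")
  doc@blocks[[1]]@categories[["atom_site"]] <- cat
  expect_error(deriveEntryFacts(doc), "undeclared asym id.*ZZ")
})

test_that("sequences are reconstructed from residues when entities are absent", {
  text <- paste0("data_p\n",
                 "loop_\n_atom_site.model_id\n_atom_site.asym_id\n",
                 "_atom_site.seq_id\n_atom_site.comp_id\n_atom_site.atom_id\n",
                 "_atom_site.type_symbol\n_atom_site.cartn_x\n_atom_site.cartn_y\n",
                 "_atom_site.cartn_z\n",
                 "m1 A 1 ALA CA C 0 0 0\nm1 A 3 GLY CA C 3.8 0 0\n")
  facts <- deriveEntryFacts(parseCif(text))
  expect_equal(facts@n_models, 1L)
  expect_equal(facts@sequences$A$one, "A-G")  # gap marked at position 2
  expect_equal(unname(facts@modeled_ranges$A[, "begin"]), c(1L, 3L))
})
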