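miniDict <- loadDictionary(file = system.file("extdata", "mini_ihm_dict.cif",
                                              package = "ihmforge"))

test_that("the bundled mini dictionary covers the whole entry layout", {
  layoutCats <- c("entry", "audit_author", "entity", "entity_seq",
                  "struct_asym", "assembly", "representation_segment",
                  "starting_model", "dataset", "model", "atom_site",
                  "sphere_site", "model_group", "state", "ordered_process",
                  "ensemble", "crosslink_restraint", "fit_metric",
                  "protocol_step", "software", "citation", "seq_reference")
  expect_true(all(layoutCats %in% dictionaryCategories(miniDict)))
  ## declared but computationally unsupported restraint categories
  expect_true(all(c("angle_restraint", "torsion_restraint") %in%
                    dictionaryCategories(miniDict)))
  for (nm in dictionaryCategories(miniDict))
    expect_gte(length(miniDict@categories[[nm]]$items), 1L)
})

test_that("dictionary load errors name the defect", {
  expect_error(loadDictionary(paste0(
    "data_d\nsave_cat_a\n_category.name a\n_category.mandatory no\nsave_\n",
    "save__a.x\n_item.category a\n_item.name x\n_item.type code\n",
    "_item.mandatory yes\n_item_linked.parent_category ghost\n",
    "_item_linked.parent_item id\nsave_\n")),
    "parent link to undefined item 'ghost.id'")
  expect_error(loadDictionary(paste0(
    "data_d\nsave_a\n_category.name a\n_category.mandatory no\nsave_\n",
    "save_a2\n_category.name a\n_category.mandatory no\nsave_\n")),
    "duplicate category definition 'a'")
  expect_error(loadDictionary(paste0(
    "data_d\nsave_a\n_category.name a\n_category.mandatory no\nsave_\n",
    "save__a.x\n_item.category a\n_item.name x\n_item.type code\n",
    "_item.mandatory yes\nsave_\n",
    "save__a.x2\n_item.category a\n_item.name x\n_item.type int\n",
    "_item.mandatory no\nsave_\n")),
    "duplicate item definition 'a.x'")
})

test_that("an empty dictionary is valid and flags everything unknown", {
  empty <- loadDictionary("")
  expect_length(dictionaryCategories(empty), 0L)
  report <- validateDocument(parseCif("data_x\n_a.b 1\n"), empty)
  expect_true(isCompliant(report))  # unknown categories are warnings only
  expect_equal(findingCounts(report)[["UNKNOWN_CATEGORY"]], 1L)
})

test_that("clean generated entries are compliant with zero findings", {
  for (seed in 1:5) {
    doc <- entryToDocument(generateEntry(randomToyConfig(seed * 17))$entry)
    report <- validateDocument(doc, miniDict)
    expect_true(isCompliant(report), info = paste("seed", seed))
    expect_equal(nrow(complianceFindings(report)), 0L)
  }
})

test_that("hand-made rule violations are each caught at their location", {
  doc <- entryToDocument(generateEntry(toyConfig(seed = 30))$entry)
  blk <- doc@blocks[[1]]

  mutate <- function(category, row, item, value, flag = 0L) {
    blk@categories[[category]] <- setCifCell(blk@categories[[category]],
                                             row, item, value, flag)
    cifDocument(list(blk))
  }
  ## mandatory citation title blanked
  f <- complianceFindings(validateDocument(mutate("citation", 1, "title", NA, 1L),
                                           miniDict))
  expect_equal(nrow(f), 1L)
  expect_equal(f$kind, "MISSING_MANDATORY_ITEM")
  expect_equal(c(f$category, f$item, f$row), c("citation", "title", "1"))

  ## negative sphere radius against the open (0, inf) bound
  f <- complianceFindings(validateDocument(mutate("sphere_site", 1, "radius", "-1.0"),
                                           miniDict))
  expect_equal(f$kind, "RANGE_VIOLATION")
  expect_equal(f$item, "radius")

  ## orphan chain id in the coordinates
  f <- complianceFindings(validateDocument(mutate("atom_site", 1, "asym_id", "Z"),
                                           miniDict))
  expect_equal(f$kind, "PARENT_MISSING")

  ## closed vocabulary on conditionality
  f <- complianceFindings(validateDocument(
    mutate("crosslink_restraint", 1, "conditionality", "some"), miniDict))
  expect_equal(f$kind, "ENUM_VIOLATION")
  expect_match(f$message, "any, all")
})

test_that("each seeded violation kind is reported exactly, and only it", {
  doc <- entryToDocument(generateEntry(toyConfig(seed = 31, n_models = 2))$entry)
  for (kind in FINDING_KINDS) {
    for (s in 1:3) {
      sv <- seedViolation(doc, kind, seed = s)
      f <- complianceFindings(validateDocument(sv$doc, miniDict))
      expect_equal(nrow(f), 1L, info = paste(kind, s))
      expect_equal(f$kind, sv$expected$kind, info = paste(kind, s))
      expect_identical(f$category, sv$expected$category)
      expect_identical(f$item, sv$expected$item)
      expect_identical(f$row, sv$expected$row)
      expect_identical(f$severity, sv$expected$severity)
    }
  }
})

test_that("adding a violation never removes an existing finding", {
  doc <- entryToDocument(generateEntry(toyConfig(seed = 32))$entry)
  one <- seedViolation(doc, "RANGE_VIOLATION", seed = 1)$doc
  f1 <- complianceFindings(validateDocument(one, miniDict))
  two <- seedViolation(one, "ENUM_VIOLATION", seed = 2)$doc
  f2 <- complianceFindings(validateDocument(two, miniDict))
  key <- function(f) paste(f$kind, f$category, f$item, f$row)
  expect_true(all(key(f1) %in% key(f2)))
  expect_equal(nrow(f2), nrow(f1) + 1L)
})

test_that("compliance reports render as text and JSON", {
  sv <- seedViolation(entryToDocument(generateEntry(toyConfig(seed = 33))$entry),
                      "ENUM_VIOLATION", seed = 1)
  report <- validateDocument(sv$doc, miniDict)
  txt <- reportToText(report)
  expect_match(txt[[1]], "NOT COMPLIANT")
  expect_match(txt[[2]], "ENUM_VIOLATION")
  parsed <- jsonlite::fromJSON(reportToJson(report))
  expect_false(parsed$compliant)
  expect_equal(parsed$counts$ENUM_VIOLATION, 1L)
})
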