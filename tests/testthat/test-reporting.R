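test_that("composition arithmetic matches a constructed multi-scale chain", {
  ## 100 residues: 1-30 atomic, 31-100 in 7 beads of 10
  fx <- generateEntry(toyConfig(seed = 60, chain_length = 100,
                                atomic_fraction = 0.3,
                                sphere_residues_per_bead = 10, n_states = 2,
                                n_models = 2))
  comp <- modelComposition(fx$entry)
  expect_equal(comp@residues_total, 100L)
  expect_equal(comp@residues_atomic, 30L)
  expect_equal(comp@residues_coarse, 70L)
  expect_equal(comp@atomic_fraction, 0.30)
  expect_equal(comp@n_spheres, 7L)   # distinct beads, not per model
  expect_equal(comp@n_atoms, 30L)
  expect_equal(comp@n_states, 2L)
  expect_equal(comp@n_models, 2L)
})

test_that("an entry with no models reports zeros", {
  entry <- ihmEntry(
    id = "E0", title = "no models",
    entities = list(list(id = "e1", kind = "polymer", polymer_type = "protein",
                         sequence = rep("GLY", 10), description = "chain")),
    asyms = data.frame(id = "A", entity_ref = "e1"))
  comp <- modelComposition(entry)
  expect_equal(comp@n_models, 0L)
  expect_equal(comp@residues_atomic, 0L)
  expect_equal(comp@residues_coarse, 0L)
  expect_equal(comp@atomic_fraction, 0)
  expect_equal(comp@residues_total, 10L)
})

test_that("residues are conserved: atomic + coarse + unmodeled = total", {
  for (seed in c(61, 62, 63)) {
    fx <- generateEntry(randomToyConfig(seed))
    comp <- modelComposition(fx$entry)
    unmodeled <- comp@residues_total - comp@residues_atomic - comp@residues_coarse
    expect_gte(unmodeled, 0L)
    expect_equal(comp@residues_atomic + comp@residues_coarse + unmodeled,
                 comp@residues_total)
    expect_equal(comp@residues_total, fx$truth$residues_total)
  }
})

test_that("single-pair satisfaction follows the threshold", {
  xs <- matrix(c(0, 10, 0, 30), nrow = 1,
               dimnames = NULL)  # residues at x = 0, 10, 0, 30
  entry <- tinyAtomicEntry(xs, rbind(tinyXlRow("1", "1", 1L, 2L, 25),
                                     tinyXlRow("2", "2", 1L, 4L, 25)))
  sat <- crosslinkSatisfaction(entry)
  out <- sat$outcomes[order(sat$outcomes$group_id), ]
  expect_equal(out$satisfied, c(TRUE, FALSE))    # 10 <= 25; 30 > 25
  expect_equal(out$min_distance, c(10, 30))
  expect_equal(sat$summary@n_satisfied, 1L)
  expect_equal(sat$summary@n_violated, 1L)
})

test_that("ambiguity groups combine members by conditionality", {
  ## one group with two member pairs at 30 and 20 Angstroms
  xs <- matrix(c(0, 30, 0, 20), nrow = 1)
  pairs <- function(cond) rbind(tinyXlRow("1", "g", 1L, 2L, 25, cond),
                                tinyXlRow("2", "g", 3L, 4L, 25, cond))
  anyRes <- crosslinkSatisfaction(tinyAtomicEntry(xs, pairs("any")))
  expect_true(anyRes$outcomes$satisfied)          # min(30, 20) = 20 <= 25
  allRes <- crosslinkSatisfaction(tinyAtomicEntry(xs, pairs("all")))
  expect_false(allRes$outcomes$satisfied)         # max(30, 20) = 30 > 25
})

test_that("ensemble rules differ between any-model and all-models", {
  xs <- rbind(c(0, 30), c(0, 20))  # model m1: 30 A, model m2: 20 A
  entry <- tinyAtomicEntry(xs, tinyXlRow("1", "g", 1L, 2L, 25))
  anyModel <- crosslinkSatisfaction(entry, list(ensemble_rule = "any-model"))
  expect_true(anyModel$outcomes$satisfied)
  expect_equal(anyModel$outcomes$best_model_ref, "m2")
  allModels <- crosslinkSatisfaction(entry, list(ensemble_rule = "all-models"))
  expect_false(allModels$outcomes$satisfied)
})

test_that("unrepresented ends and non-upper-bound forms are set aside", {
  xs <- matrix(c(0, 10), nrow = 1)
  xl <- rbind(tinyXlRow("1", "1", 1L, 2L, 25),
              tinyXlRow("2", "2", 1L, 2L, 25, form = "harmonic"))
  xl$seq_id_2[1] <- 2L
  entry <- tinyAtomicEntry(xs, xl, len = 5L)  # residues 3-5 have no coordinates
  entry@crosslinks$seq_id_2[1] <- 5L          # end with no atom or sphere
  sat <- crosslinkSatisfaction(entry)
  expect_equal(sat$findings$group_id, "1")
  expect_match(sat$findings$message, "unrepresented")
  expect_equal(sat$summary@n_groups, 0L)
  expect_equal(sat$not_evaluated, "2")
})

test_that("fixture satisfaction counts match the brute-force oracle", {
  for (seed in c(64, 65)) {
    cfg <- randomToyConfig(seed)
    fx <- generateEntry(cfg)
    if (fx$truth$n_satisfied + fx$truth$n_violated == 0) next
    for (rule in c("any-model", "all-models")) {
      sat <- crosslinkSatisfaction(fx$entry, list(ensemble_rule = rule))
      orc <- bruteForceSatisfaction(fx$entry, rule)
      expect_equal(sat$summary@n_satisfied, orc$n_satisfied)
      expect_equal(sat$summary@n_violated, orc$n_violated)
      expect_equal(sat$summary@n_satisfied, fx$truth$n_satisfied)
      expect_equal(sat$summary@n_violated, fx$truth$n_violated)
    }
  }
})

catalogFixture <- function() {
  mk <- function(acc, title, types, sw, authors, ms, mst, ord)
    data.frame(accession = acc, title = title, summary = paste(title, "summary"),
               data_types = I(list(types)), software_names = I(list(sw)),
               authors = I(list(authors)), multi_scale = ms, multi_state = mst,
               ordered = ord, stringsAsFactors = FALSE)
  catalogBind(
    mk("PDBDEV_00000001", "nuclear pore complex", c("CX-MS", "SAS"),
       c("IMP"), c("Doe, Jane"), TRUE, FALSE, FALSE),
    mk("PDBDEV_00000002", "Nup84 subcomplex", c("CX-MS"),
       c("IMP", "IMP"), c("Roe, Richard"), FALSE, TRUE, FALSE),
    mk("PDBDEV_00000003", "exosome complex", c("3DEM"),
       c("ROSETTA"), c("Doe, Jane"), FALSE, TRUE, TRUE))
}

test_that("archive statistics bucket entries once per distinct value", {
  stats <- archiveStatistics(catalogFixture())
  expect_equal(stats@n_entries, 3L)
  expect_equal(stats@counts_by_data_type,
               c("CX-MS" = 2L, "3DEM" = 1L, "SAS" = 1L))
  ## IMP listed twice in one entry still counts once
  expect_equal(stats@counts_by_software, c(IMP = 2L, ROSETTA = 1L))
  ## column sums equal the per-entry distinct-type totals
  expect_equal(sum(stats@counts_by_data_type),
               sum(vapply(catalogFixture()$data_types,
                          function(x) length(unique(x)), integer(1))))
  empty <- archiveStatistics(catalogFixture()[0, ])
  expect_equal(empty@n_entries, 0L)
  expect_length(empty@counts_by_data_type, 0L)
})

test_that("search supports boolean operators, wildcards and facets", {
  cat <- catalogFixture()
  expect_equal(searchCatalog(cat, "nuclear AND pore"), "PDBDEV_00000001")
  expect_equal(searchCatalog(cat, "nup*"), "PDBDEV_00000002")  # case-folded
  expect_equal(searchCatalog(cat, "complex OR nup*"),
               c("PDBDEV_00000001", "PDBDEV_00000002", "PDBDEV_00000003"))
  expect_equal(searchCatalog(cat, "CX-MS", facets = list(multi_state = TRUE)),
               "PDBDEV_00000002")
  expect_equal(searchCatalog(cat, "", facets = list(data_type = "3DEM")),
               "PDBDEV_00000003")
  expect_equal(searchCatalog(cat, "complex AND NOT exosome"), "PDBDEV_00000001")
  expect_error(searchCatalog(cat, "(nuclear AND"), "unbalanced|unexpected end")
  expect_error(searchCatalog(cat, ""), "query or at least one facet")
  expect_error(searchCatalog(cat, "a", facets = list(bogus = 1)), "unknown facet")
})

test_that("search satisfies De Morgan duality on the fixture catalog", {
  cat <- catalogFixture()
  all <- cat$accession
  lhs <- searchCatalog(cat, "NOT (complex OR nup*)")
  rhs <- setdiff(all, searchCatalog(cat, "complex OR nup*"))
  expect_equal(lhs, sort(rhs))
  lhs2 <- searchCatalog(cat, "NOT complex AND NOT nup*")
  expect_equal(lhs, lhs2)
})

test_that("entry summaries derive flags and propagate data types", {
  fx <- generateEntry(toyConfig(seed = 66, n_states = 2, ordered = TRUE))
  ce <- entrySummary(fx$entry, "PDBDEV_00000042")
  expect_true(ce$multi_scale)   # atoms and spheres both present
  expect_true(ce$multi_state)
  expect_true(ce$ordered)
  expect_setequal(ce$data_types[[1]], unique(fx$entry@datasets$data_type))

  atomicOnly <- generateEntry(toyConfig(seed = 67, atomic_fraction = 1,
                                        n_crosslinks_satisfied = 2,
                                        n_crosslinks_violated = 0))$entry
  ce2 <- entrySummary(atomicOnly, "PDBDEV_00000043")
  expect_false(ce2$multi_scale)
  expect_false(ce2$multi_state)
  expect_false(ce2$ordered)
})

test_that("catalogs survive JSON persistence", {
  cat <- catalogFixture()
  path <- withr::local_tempfile(fileext = ".json")
  writeCatalog(cat, path)
  back <- readCatalog(path)
  expect_equal(back$accession, cat$accession)
  expect_equal(back$data_types, cat$data_types, ignore_attr = TRUE)
  expect_equal(searchCatalog(back, "nuclear AND pore"), "PDBDEV_00000001")
})
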