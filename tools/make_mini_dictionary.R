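#!/usr/bin/env Rscript
## Regenerates inst/extdata/mini_ihm_dict.cif from the definition table
## below. Run from the repository root: Rscript tools/make_mini_dictionary.R

suppressMessages(devtools::load_all(".", quiet = TRUE))

it <- function(name, type, mand = TRUE, enum = NULL, range = NULL,
               open = c(FALSE, FALSE), parent = NULL, desc = NULL) {
  list(name = name, type = type, mand = mand, enum = enum, range = range,
       open = open, parent = parent, desc = desc)
}

yesno <- c("yes", "no")
dataTypes <- c("CX-MS", "3DEM", "2DEM", "SAS", "NMR", "X-ray", "FRET", "EPR",
               "HDX-MS", "other")
dbNames <- c("PDB", "BMRB", "EMDB", "EMPIAR", "SASBDB", "ProteomeXchange",
             "ModelArchive")

defs <- list(
  list(name = "entry", mand = TRUE, key = "id", items = list(
    it("id", "code", desc = "entry identifier; names the data block"),
    it("title", "text"),
    it("summary", "text", mand = FALSE))),
  list(name = "audit_author", mand = TRUE, key = "ordinal", items = list(
    it("ordinal", "int", range = c(1, NA)),
    it("name", "text"))),
  list(name = "citation", mand = TRUE, key = "id", items = list(
    it("id", "code"),
    it("title", "text"),
    it("journal", "text"),
    it("doi", "code", mand = FALSE),
    it("pmid", "code", mand = FALSE))),
  list(name = "citation_author", mand = FALSE, key = c("citation_id", "ordinal"),
       items = list(
    it("citation_id", "code", parent = c("citation", "id")),
    it("ordinal", "int", range = c(1, NA)),
    it("name", "text"))),
  list(name = "software", mand = FALSE, key = "id", items = list(
    it("id", "code"),
    it("name", "text"),
    it("version", "code", mand = FALSE),
    it("classification", "text"),
    it("location", "text", mand = FALSE))),
  list(name = "entity", mand = TRUE, key = "id", items = list(
    it("id", "code"),
    it("type", "code", enum = c("polymer", "nonpolymer", "water")),
    it("polymer_type", "code", mand = FALSE,
       enum = c("protein", "RNA", "DNA", "other")),
    it("description", "text", mand = FALSE))),
  list(name = "entity_seq", mand = FALSE, key = c("entity_id", "num"), items = list(
    it("entity_id", "code", parent = c("entity", "id")),
    it("num", "int", range = c(1, NA)),
    it("comp_id", "code"))),
  list(name = "struct_asym", mand = TRUE, key = "id", items = list(
    it("id", "code"),
    it("entity_id", "code", parent = c("entity", "id")))),
  list(name = "assembly", mand = FALSE, key = c("id", "asym_id", "seq_begin"),
       items = list(
    it("id", "code"),
    it("asym_id", "code", parent = c("struct_asym", "id")),
    it("seq_begin", "int", range = c(1, NA)),
    it("seq_end", "int", range = c(1, NA)))),
  list(name = "representation_segment", mand = FALSE,
       key = c("representation_id", "asym_id", "seq_begin"), items = list(
    it("representation_id", "code"),
    it("asym_id", "code", parent = c("struct_asym", "id")),
    it("seq_begin", "int", range = c(1, NA)),
    it("seq_end", "int", range = c(1, NA)),
    it("mode", "code", enum = c("atomic", "sphere")),
    it("granularity", "code", enum = c("by-residue", "by-feature")),
    it("is_rigid", "code", enum = yesno),
    it("starting_model_id", "code", mand = FALSE,
       parent = c("starting_model", "id")))),
  list(name = "starting_model", mand = FALSE, key = "id", items = list(
    it("id", "code"),
    it("asym_id", "code", parent = c("struct_asym", "id")),
    it("seq_begin", "int", range = c(1, NA)),
    it("seq_end", "int", range = c(1, NA)),
    it("source_type", "code",
       enum = c("experimental", "comparative", "ab-initio", "other")),
    it("dataset_id", "code", mand = FALSE, parent = c("dataset", "id")))),
  list(name = "dataset", mand = FALSE, key = "id", items = list(
    it("id", "code"),
    it("data_type", "code", enum = dataTypes),
    it("db_name", "code", mand = FALSE, enum = dbNames),
    it("accession", "code", mand = FALSE),
    it("doi", "code", mand = FALSE),
    it("file_path", "text", mand = FALSE))),
  list(name = "model", mand = FALSE, key = "id", items = list(
    it("id", "code"),
    it("assembly_id", "code", parent = c("assembly", "id")),
    it("representation_id", "code",
       parent = c("representation_segment", "representation_id")),
    it("protocol_id", "code", mand = FALSE,
       parent = c("protocol_step", "protocol_id")))),
  list(name = "atom_site", mand = FALSE,
       key = c("model_id", "asym_id", "seq_id", "atom_id"), items = list(
    it("model_id", "code", parent = c("model", "id")),
    it("asym_id", "code", parent = c("struct_asym", "id")),
    it("seq_id", "int", range = c(1, NA)),
    it("comp_id", "code"),
    it("atom_id", "code"),
    it("type_symbol", "code"),
    it("cartn_x", "float"),
    it("cartn_y", "float"),
    it("cartn_z", "float"))),
  list(name = "sphere_site", mand = FALSE,
       key = c("model_id", "asym_id", "seq_begin"), items = list(
    it("model_id", "code", parent = c("model", "id")),
    it("asym_id", "code", parent = c("struct_asym", "id")),
    it("seq_begin", "int", range = c(1, NA)),
    it("seq_end", "int", range = c(1, NA)),
    it("cartn_x", "float"),
    it("cartn_y", "float"),
    it("cartn_z", "float"),
    it("radius", "float", range = c(0, NA), open = c(TRUE, FALSE),
       desc = "bead radius in Angstroms; strictly positive"),
    it("rmsf", "float", mand = FALSE, range = c(0, NA)))),
  list(name = "model_group", mand = FALSE, key = "id", items = list(
    it("id", "code"),
    it("name", "text", mand = FALSE))),
  list(name = "model_group_link", mand = FALSE, key = c("group_id", "model_id"),
       items = list(
    it("group_id", "code", parent = c("model_group", "id")),
    it("model_id", "code", parent = c("model", "id")))),
  list(name = "state", mand = FALSE, key = "id", items = list(
    it("id", "code"),
    it("name", "text", mand = FALSE),
    it("population_fraction", "float", mand = FALSE, range = c(0, 1)))),
  list(name = "state_link", mand = FALSE, key = c("state_id", "group_id"),
       items = list(
    it("state_id", "code", parent = c("state", "id")),
    it("group_id", "code", parent = c("model_group", "id")))),
  list(name = "state_group", mand = FALSE, key = "id", items = list(
    it("id", "code"))),
  list(name = "state_group_link", mand = FALSE,
       key = c("state_group_id", "state_id"), items = list(
    it("state_group_id", "code", parent = c("state_group", "id")),
    it("state_id", "code", parent = c("state", "id")))),
  list(name = "ordered_process", mand = FALSE, key = "id", items = list(
    it("id", "code"),
    it("ordered_by", "code", enum = c("time", "other")))),
  list(name = "ordered_step", mand = FALSE, key = c("process_id", "step_index"),
       items = list(
    it("process_id", "code", parent = c("ordered_process", "id")),
    it("step_index", "int", range = c(1, NA)),
    it("from_group_id", "code", parent = c("model_group", "id")),
    it("to_group_id", "code", parent = c("model_group", "id")))),
  list(name = "ensemble", mand = FALSE, key = "id", items = list(
    it("id", "code"),
    it("group_id", "code", parent = c("model_group", "id")),
    it("num_models_total", "int", range = c(0, NA)),
    it("num_models_deposited", "int", range = c(0, NA)),
    it("clustering_method", "text", mand = FALSE))),
  list(name = "crosslink_restraint", mand = FALSE, key = "id", items = list(
    it("id", "code"),
    it("group_id", "code",
       desc = "ambiguity group; members share one experimental observation"),
    it("entity_id_1", "code", parent = c("entity", "id")),
    it("asym_id_1", "code", mand = FALSE, parent = c("struct_asym", "id")),
    it("seq_id_1", "int", range = c(1, NA)),
    it("atom_id_1", "code", mand = FALSE),
    it("entity_id_2", "code", parent = c("entity", "id")),
    it("asym_id_2", "code", mand = FALSE, parent = c("struct_asym", "id")),
    it("seq_id_2", "int", range = c(1, NA)),
    it("atom_id_2", "code", mand = FALSE),
    it("linker", "code"),
    it("threshold_a", "float", range = c(0, NA), open = c(TRUE, FALSE),
       desc = "distance threshold in Angstroms"),
    it("restraint_form", "code",
       enum = c("upper-bound", "lower-bound", "harmonic")),
    it("granularity", "code", enum = c("by-residue", "by-atom")),
    it("conditionality", "code", enum = c("any", "all")),
    it("dataset_id", "code", parent = c("dataset", "id")))),
  list(name = "angle_restraint", mand = FALSE, key = "id", items = list(
    it("id", "code"),
    it("group_id", "code"),
    it("angle_deg", "float", mand = FALSE),
    it("dataset_id", "code", parent = c("dataset", "id")))),
  list(name = "torsion_restraint", mand = FALSE, key = "id", items = list(
    it("id", "code"),
    it("group_id", "code"),
    it("torsion_deg", "float", mand = FALSE),
    it("dataset_id", "code", parent = c("dataset", "id")))),
  list(name = "fit_metric", mand = FALSE, key = character(0), items = list(
    it("restraint_kind", "code", enum = c("3DEM", "2DEM", "SAS", "EPR")),
    it("dataset_id", "code", parent = c("dataset", "id")),
    it("model_id", "code", parent = c("model", "id")),
    it("metric_name", "text"),
    it("metric_value", "float"))),
  list(name = "protocol_step", mand = FALSE, key = c("protocol_id", "step_index"),
       items = list(
    it("protocol_id", "code"),
    it("step_index", "int", range = c(1, NA)),
    it("method_name", "text"),
    it("num_models_begin", "int", range = c(0, NA)),
    it("num_models_end", "int", range = c(0, NA)),
    it("multi_scale", "code", enum = yesno),
    it("multi_state", "code", enum = yesno),
    it("ordered", "code", enum = yesno),
    it("software_id", "code", mand = FALSE, parent = c("software", "id")),
    it("dataset_ids", "code", mand = FALSE,
       desc = "comma-separated dataset ids used by this step"))),
  list(name = "seq_reference", mand = FALSE,
       key = c("entity_id", "db_name", "accession"), items = list(
    it("entity_id", "code", parent = c("entity", "id")),
    it("db_name", "code", enum = c("UniProt", "INSDC")),
    it("accession", "code"),
    it("model_begin", "int", range = c(1, NA)),
    it("model_end", "int", range = c(1, NA)),
    it("ref_begin", "int", range = c(1, NA)),
    it("ref_end", "int", range = c(1, NA)),
    it("identity_percent", "float", range = c(0, 100))))
)

ny <- function(x) if (x) "yes" else "no"
frames <- list()
for (d in defs) {
  cats <- list(cifCategory("category", list(name = d$name, mandatory = ny(d$mand))))
  if (length(d$key))
    cats <- c(cats, list(cifCategory("category_key", list(item = d$key))))
  frames[[length(frames) + 1L]] <- cifBlock(d$name, cats)
  for (i in d$items) {
    icats <- list(cifCategory("item", c(
      list(category = d$name, name = i$name, type = i$type,
           mandatory = ny(i$mand)),
      if (!is.null(i$desc)) list(description = i$desc))))
    if (!is.null(i$enum))
      icats <- c(icats, list(cifCategory("item_enumeration", list(value = i$enum))))
    if (!is.null(i$range)) {
      flags <- matrix(ifelse(is.na(c(i$range, "y", "y")), CIF_INAPPLICABLE,
                             CIF_TEXT), nrow = 1)
      icats <- c(icats, list(cifCategory("item_range", list(
        min = if (is.na(i$range[[1]])) NA_character_ else ihmforge:::fmtNum(i$range[[1]]),
        max = if (is.na(i$range[[2]])) NA_character_ else ihmforge:::fmtNum(i$range[[2]]),
        min_open = ny(i$open[[1]]), max_open = ny(i$open[[2]])))))
    }
    if (!is.null(i$parent))
      icats <- c(icats, list(cifCategory("item_linked", list(
        parent_category = i$parent[[1]], parent_item = i$parent[[2]]))))
    frames[[length(frames) + 1L]] <- cifBlock(paste0("_", d$name, ".", i$name), icats)
  }
}

block <- cifBlock("mini_ihm_dict",
                  list(cifCategory("dictionary",
                                   list(title = "mini-ihm", version = "1.0"))),
                  frames)
writeCif(cifDocument(list(block)), "inst/extdata/mini_ihm_dict.cif")
cat("wrote inst/extdata/mini_ihm_dict.cif\n")
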