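---
title: "Archiving integrative structures: data model, validation and workflow"
author: "ihmforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Archiving integrative structures: data model, validation and workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihmforge)
```

## The problem

Integrative (hybrid) structural models combine spatial restraints from many
experimental sources — chemical cross-linking mass spectrometry (CX-MS),
electron microscopy, small-angle scattering, FRET, EPR, hydrogen–deuterium
exchange and more — with experimentally determined or predicted component
structures. The results are unlike classical crystallographic entries: they
can be *multi-scale* (atomic regions mixed with coarse-grained beads),
*multi-state* (several conformational or compositional states),
*ordered* (states related in time or along a pathway) and deposited as
*ensembles*. Archiving them requires a data model that represents all of
this plus the restraints, starting models, external dataset references and
modeling protocols; a machine-readable dictionary that makes compliance
checkable by software; a deposition workflow that harvests heterogeneous
files and metadata from depositors into one coherent archival file; and
curation and reporting procedures on top.

`ihmforge` implements that whole stack as a self-contained R package: every
layer is real, testable code, and a deterministic fixture generator stands
in for live depositions so the pipeline can be exercised offline.

## The mmCIF layer

All archival data are physically encoded in the PDBx/mmCIF dialect of the
STAR syntax: `data_` blocks containing categories of named items, written
either key–value or as `loop_` tables, with `'...'`/`"..."` quoting,
semicolon-fenced multi-line values and the two sentinels `?` (value
unknown) and `.` (inapplicable). The parser (`parseCif()`) accepts this
subset permissively (keywords are case-insensitive, values are kept as
uninterpreted text) and reports syntax errors with line numbers; the writer
(`writeCif()`) is conservative: values with whitespace or leading special
characters are quoted, values with newlines or unquotable quote
combinations are fenced, one-row categories are written key–value and
multi-row categories as loops.

Two design points deserve a note:

* **Semantic equality.** A round-trip contract needs an equality notion the
  format itself never states. `cifEquals()` ignores quoting style,
  whitespace, comments, item order within a category and category order
  within a block; it respects block order, row order and cell content, and
  it distinguishes `?` from `.`. This is the contract the round-trip
  properties are tested against.
* **A dialect limit.** A text value containing a newline immediately
  followed by a semicolon cannot be written in a semicolon fence; the
  writer refuses it with an explicit error rather than silently corrupting
  the file. Typed values never hit this (typing is the dictionary layer's
  job; at this layer everything is text). Output line length is not
  limited.

Values are typed only by the dictionary; keeping the syntax layer untyped is
what makes lossless passthrough of unknown categories possible.

## The entry data model

`IhmEntry` is the domain object graph of one deposition: entities (unique
molecular sequences) and asym units (placed chains), the modeled assembly,
a multi-scale representation (atomic segments by residue, sphere segments
by feature), per-model coordinates (atoms and coarse-grained spheres with
radius and optional RMSF), model groups, states, state groups, ordered
processes, ensembles, external datasets (database references from a
controlled list, or DOIs), starting models, cross-link restraints with
ambiguity groups, depositor-provided fit metrics, protocol steps, software,
citations and reference-sequence annotations.

The serialization (`entryToDocument()` / `entryFromDocument()`) uses a
fixed, documented category layout — one category per collection, e.g.
`entity`, `entity_seq`, `struct_asym`, `assembly`,
`representation_segment`, `model`, `atom_site`, `sphere_site`,
`model_group`, `state`, `ordered_process`, `ensemble`,
`crosslink_restraint`, `fit_metric`, `protocol_step`, `software`,
`citation`, `citation_author`, `seq_reference` — in a single data block
named after the entry id. The layout is this package's own: the point is a
self-contained, dictionary-checkable convention mirroring the content an
integrative-modeling archive must carry, not a replica of any external
dictionary. Conventions: residue indices are 1-based with inclusive
ranges; coordinates are Cartesian ångströms; absent optional values are
written as `.`; numbers are rendered with up to six trimmed decimals, so
values kept at three decimals (as the fixture generator does) survive a
parse/format cycle exactly. Categories the model does not interpret are
retained opaquely and re-emitted on write — an archive must not destroy
depositor data. Serialization is deterministic: the same entry yields
byte-identical text, which makes file hashes meaningful.

Angle and torsion restraint categories are declared in the dictionary
layout, but only distance-type (cross-link) restraints have computational
support; no evaluation semantics are defined here for the other forms.
Multi-state population fractions are optional and only required to sum to
at most one within a state group. A deposition document must contain
exactly one data block.

## The dictionary engine

The validation dictionary is itself an mmCIF-dialect file using STAR save
frames: one frame per category (name, mandatory flag, key items) and one
per item (type, mandatory flag, optional enumeration, optional numeric
range with open/closed bounds, optional parent link, description). Types
are `int` (pure decimal), `float` (scientific notation accepted), `code`
(no embedded whitespace), `text` and `yyyy-mm-dd`.

`validateDocument()` checks every rule class per row: mandatory categories
and items (a `?` or `.` does **not** satisfy a mandatory item — "filled"
is read strictly), type validity, controlled vocabularies, boundary
conditions, parent–child relationships between data items (every child
value must appear among its parent item's values) and key-tuple
uniqueness. All outcomes are findings with exact locations (block,
category, item, row), never exceptions; a report is compliant iff it has
no error-severity findings. Categories and items absent from the
dictionary are warnings, not errors, because the data standard is expected
to grow as new kinds of structures are deposited.

The bundled `mini_ihm_dict.cif` covers every category of the entry layout
(30 categories, ~140 item definitions). Its specific mandatory-item
choices are documented assumptions of this package, not claims about any
production archive's rules. The violation seeder (`seedViolation()`)
closes the loop for testing: it injects exactly one violation of a chosen
kind at a pseudo-random eligible location chosen so no *other* rule can
fire (for example, the mandatory category it removes is one no child link
points at), and returns the finding the validator must report.

## The harvesting workflow

A deposition is a `Submission` moving through a seven-status state
machine:

| from  | action               | to     |
|-------|----------------------|--------|
| —     | create               | DRAFT  |
| DRAFT / ANNOT / ERROR | process (model upload) | PROC |
| PROC  | processing succeeds  | ANNOT  |
| PROC  | processing fails     | ERROR  |
| ANNOT | submit, aggregate compliant | SUBMIT |
| ANNOT | submit, aggregate non-compliant | ERROR |
| SUBMIT| release immediately  | REL    |
| SUBMIT| hold for publication | HOLD   |
| HOLD  | publication released | REL    |

`PROC`, `ERROR` and `SUBMIT` are the archive's communication vocabulary
between depositors, curators and software agents; `DRAFT`, `ANNOT`, `HOLD`
and `REL` close the lifecycle into a total machine. Any (status, action)
pair not in the table is an invalid transition, and the history is
append-only, so the whole path of a deposition is auditable. By
construction no path reaches `SUBMIT` from `DRAFT` or from `ERROR` without
passing through `PROC` — a fixed file must always be re-processed.

Around the machine sit the storage and metadata services:

* **Files** are content-addressed: SHA-256 hashes are stored alongside the
  bytes and re-verified on read, so any corruption is detected; re-uploads
  of the same (name, role) increment a version and keep prior versions
  retrievable.
* **Metadata records** (authors, citations, protocols, reference-sequence
  and dataset references) are validated on entry against the dictionary's
  per-category rules — mandatory items, types, vocabularies, ranges — and
  stored as immutable, versioned snapshots (`getSnapshot()` reconstructs
  any point in time). Parent links are not checked at this stage because a
  single section carries no cross-category context; they are enforced on
  the aggregate at submission. A rejected payload changes nothing.
* **Restraints** arrive as CSV/TSV files against a documented template
  (`crosslinkCsvColumns()`); the delimiter is sniffed. Ingestion is atomic
  — one bad row rejects the file with line-numbered findings, matching the
  fix-and-re-upload interaction — and each row's component id is
  cross-checked against the entity sequence at that position. Asym units
  are resolved automatically when an entity has exactly one chain.
* **Submission** merges the processed model entry, the latest version of
  each metadata section and the ingested restraints into one aggregate
  entry, serializes it, stores it (hashed, like everything else) and
  validates it against the dictionary. The gate requires the authors and
  citations sections, either recorded in the workflow or already present
  in the uploaded file — the latter is the bypass path for depositors
  whose modeling software already writes complete compliant files.

Access control is modeled as data, not authentication: a submission is
visible to its depositor and to any curator/administrator
(`submissionVisible()`).

## Curation

**Reference sequences.** Chains are matched to their reference database
sequences with an exact semi-global dynamic-programming aligner
(`alignToReference()`): the model sequence aligns in full, reference
overhangs are free, gaps are linear (defaults match +1 / mismatch −1 /
gap −2). Determinism is part of the contract: among equal-scoring
reference end columns the smallest is chosen, and traceback prefers
diagonal, then up (gap in reference), then left (gap in model). At
archive-entry scale — one candidate reference per chain, with the question
"do these match and over which region" — an exact aligner is preferable
to a heuristic database search: no statistics, no database, same
annotation output (spans and identity). Identity is
100·matches/(matches+mismatches+gaps); `annotateReference()` attaches the
reference (database, accession, aligned spans, identity) when identity
reaches the threshold, 95% by default (a configurable curation assumption;
no standard value exists), and otherwise raises a sequence-mismatch
finding and leaves the entry untouched.

**Small molecules.** `checkChemComp()` verifies that every non-polymer
component is present in a component dictionary and that its entry-level
name matches (case-insensitively) the dictionary name. The bundled
`mini_ccd.cif` is a ~20-component synthetic stand-in; a full component
file can be supplied instead.

**Accessions and release.** Accession codes are sequential, sortable
`PDBDEV_` + eight digits, issued from a JSON-file registry atomically
(write-to-temp, rename) and idempotently per entry. Accessions are issued
at curation here (issuance at submission is a plausible alternative the
field is still converging on). Release follows depositor instructions:
immediately upon completion of processing, or held (`HOLD`) until the
associated publication appears.

## Reporting

**Model composition** counts a residue as atomic if any atom with its
residue index exists in any model, and as coarse-grained if a sphere
covers it and it is not atomic; totals come from entity lengths over all
chains, so unmodeled residues are visible as the difference. Atom/sphere
counts are distinct representation positions, not multiplied by ensemble
size.

**Cross-link satisfaction.** Restraints sharing a group id form one
ambiguity group (one experimental observation with several possible
assignments). Per model, member pair distances combine under the group's
conditionality — `any` takes the minimum, `all` the maximum — and the
group is satisfied in a model iff that distance is within the threshold
(upper-bound form only; lower-bound and harmonic restraints are stored and
reported as not evaluated). The representative point of a residue falls
back along: the named atom (for by-atom restraints) → the residue's CA
atom → the center of the sphere covering the residue, with no radius
correction on sphere distances. When a restraint end names no asym unit,
the distance is minimized over the entity's chains. Under the default
`any-model` ensemble rule a group is satisfied if at least one deposited
model satisfies it — the usual convention for ensemble restraint
reporting — with `all-models` available in the policy object. Ends not
represented by any atom or sphere yield an explicit finding and exclude
the group from the counts rather than silently defaulting.

**Catalog.** `entrySummary()` builds the searchable record (title,
composed summary, authors, software, data types, and flags: multi-scale
iff atomic and sphere segments coexist, multi-state iff ≥ 2 states,
ordered iff an ordered process exists). `archiveStatistics()` buckets
entries once per distinct data type and software. `searchCatalog()`
implements a small query language — terms matched case-insensitively
against words of the text fields, `AND`/`OR`/`NOT`, parentheses,
trailing-`*` wildcards, adjacency meaning `AND` — plus facet filters that
intersect the query results. Malformed queries fail with a position.

## The fixture generator

`generateEntry(toyConfig(...))` is the package's synthetic study system.
Defaults describe the reference fixture: one 100-residue protein chain,
30% atomic, the rest in 10-residue beads, one model, 15 satisfied and 5
violated cross-links at a 25 Å threshold (a typical CA–CA cutoff for a
DSS-class cross-linker). Atomic regions are CA traces on an approximately
self-avoiding random walk (3.8 Å steps, rejection up to 100 tries against
a 3 Å exclusion radius, then relax); beads continue the walk at larger
step. Cross-links are placed *by construction*: each group moves one
unique endpoint to exactly 0.5× (satisfied) or 1.5× (violated) of the
threshold from its anchor in **every** model, so the expected counts hold
under any conditionality or ensemble rule; anchors may be shared but are
never moved. Coordinates are rounded to 3 decimals after placement (the
0.5×/1.5× margins dwarf the rounding). Everything the generator decides is
echoed in a ground-truth record, and the central test suite checks that
the production operations — `deriveEntryFacts()`, `modelComposition()`,
`crosslinkSatisfaction()` — recover it exactly over random configurations.

What the generator does *not* emulate: physically realistic conformations,
real sequence statistics (uniform 20-letter draws), experimental noise in
restraint lists, heterogeneous per-state assemblies, or the long tail of
real-world mmCIF formatting. Passing tests therefore demonstrate the
correctness of the bookkeeping, validation logic and the satisfaction
arithmetic — not robustness to adversarial real-world files beyond the
quoting/fencing stress that `generateRandomDocument()` covers.

## Problem sizes and numerical choices

The test suite runs the round-trip property over 100 random stress
documents, validator completeness over nine violation kinds × 20 base
entries plus 50 clean entries, aligner equivalence against an exhaustive
alignment enumeration on 100 small pairs (model ≤ 6, reference ≤ 12 —
enumeration over order-preserving position mappings is exact there) and an
independent dynamic-programming implementation up to length 50,
cross-link satisfaction against a brute-force per-pair/per-model scan on
20 entries up to 200 groups and 10 models, and ground-truth recovery over
50 random configurations. These sizes were chosen as the points where the
properties are exercised at full structural variety while the whole suite
stays comfortably interactive.

Numeric comparisons in entry equality use a 10⁻⁶ tolerance (matching the
six-decimal serialization); satisfaction comparisons are exact because the
construction places distances at half or 1.5 times the threshold. Ties in
the aligner are broken deterministically as described above; the
brute-force oracle reports the full set of optimal identities, and the
implementation's choice must lie in it.

## Limitations

* The dictionary dialect implements the rule classes needed here (types,
  vocabularies, ranges, parents, keys, mandatory) — not the full DDL
  machinery of production archives (no sub-category aggregates, no method
  expressions, no save-frame-free dictionaries).
* Only upper-bound distance restraints are evaluated; experiment-specific
  model quality (SAS χ², EM cross-correlation) is out of scope, and fit
  metrics are echoed as depositor-provided values, never computed.
* The workflow is single-process and in-memory by design; persistence is
  limited to the accession registry and catalog JSON files plus the CLI's
  file outputs. There is no real authentication, no concurrency and no
  web interface.
* The search index is in-memory and rebuilt per query; fine for an archive
  of hundreds of entries, not for millions.
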