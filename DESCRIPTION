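Package: ihmforge
Title: Archiving Toolkit for Integrative and Hybrid Structural Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained implementation of an archiving system for
    integrative/hybrid structural models: lossless reading and writing of
    PDBx/mmCIF (STAR-syntax) files, an S4 domain model for multi-scale,
    multi-state and ordered structural ensembles with heterogeneous spatial
    restraints, a dictionary-driven compliance validator, a data-harvesting
    deposition workflow modelled as an auditable state machine with
    content-addressed file storage and versioned metadata records, curation
    procedures (reference-sequence alignment, small-molecule nomenclature
    checks, accession issuance, release), and reporting tools (model
    composition, cross-link restraint satisfaction, archive statistics and a
    boolean/wildcard catalog search). Deterministic synthetic-entry fixtures
    make every component testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    digest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    openssl,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
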