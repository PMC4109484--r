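Package: contax
Title: Taxonomic Concept Trees, Fractional-Weight Validation and
    Checklist Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Manages taxonomic concepts (circumscriptions) rather than
    scientific names. Each distinct circumscription receives an opaque
    hexadecimal identifier; parent-child relationships between identifiers
    are organized into concept trees that may carry alternate variants when
    contradictory arrangements have been published. Exact fractional
    weights (rational arithmetic, root weight 1) validate whether a
    checklist's species and subspecies form a complete arrangement, and a
    combinatorial solver maps the names of a published checklist onto
    concept identifiers, reporting new, ambiguous or conflicting concepts.
    Includes Darwin Core flavoured checklist readers, a tree-store format,
    worked fixtures from the bird taxonomy literature and a simulator that
    generates checklist histories with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
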