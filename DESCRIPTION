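Package: aquaprof
Title: Mechanistically Grounded Structural Profiling of Aquatic Toxicants
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens chemical inventories against a tiered knowledge base of
    structural alerts anchored in molecular initiating events, assigning
    compounds to a three-domain hierarchy (narcosis / reactive / specific)
    with mechanistic groups and subgroups beneath. Alerts are ordered SMARTS
    conjunctions with optional exclusion patterns, applied in a two-phase
    sequential workflow in which reactive, specific and enhanced-narcosis
    rules are evaluated first and only unmatched compounds fall through to
    the nonpolar-narcosis rules. Includes SMILES standardization (salt
    stripping, stereochemistry removal, canonicalization, duplicate and
    inorganic removal) with an auditable rejection log, inventory-level
    coverage reporting (alert-count histograms, Sankey flow tables, domain
    proportions), and harmonization of external classification-scheme
    outputs onto the three broad domains for concordance analysis.
    Substructure matching and SMILES canonicalization use Open Babel via
    ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    yaml,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
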