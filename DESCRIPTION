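Package: herbid
Title: DNA Barcode Reference Libraries and Species Identification for
    Herbal Drug Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates DNA barcode reference libraries for
    pharmacopeia herbal drugs (taxonomy, specimen, sequence and reference
    records with synonym-aware nomenclature), compiles them into searchable
    barcode databases, and identifies unknown market samples from ITS2 or
    psbA-trnH reads through a pipeline of quality control, marker detection,
    core-region trimming, chloroplast inversion normalization, k-mer seeded
    nearest-neighbour search, Kimura 2-parameter distances, neighbour-joining
    trees and rule-based taxonomic assignment.  Also provides barcode-gap
    divergence analytics (theta, theta prime, coalescent depth and related
    statistics), pharmacopeia origin-difference classification, and a seeded
    simulator of reference libraries and query sets with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    yaml
Config/testthat/edition: 3
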