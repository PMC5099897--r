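Package: exoprov
Title: Cellular-Source Provenance Analysis of Extracellular-Vesicle Cargo
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies the likely cellular source of extracellular-vesicle
    (exosome) cargo proteins by thresholding against a categorized gene
    expression atlas. Collapses probe-level atlas measurements to one row per
    gene, calls a protein "expressed" in a category when its value exceeds a
    multiple (default 3) of the protein's median across categories, aggregates
    category calls into candidate source-cell groups, and censuses the
    resulting multi-set Venn partition. Also compares miRNA intensity tables
    between two conditions (spike-in scaling, presence calls, unique/shared
    sets, fold-enrichment counts) and ships a synthetic-data generator with
    ground-truth labels so every stage can be tested without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
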