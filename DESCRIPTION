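Package: allnet
Title: Network-Based Prioritization of Acute Lymphoblastic Leukemia Cancer Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for prioritizing acute lymphoblastic leukemia (ALL) cancer
    genes and candidate genes from somatic mutation catalogs and
    protein-protein interaction (PPI) evidence. Summarizes per-gene mutation
    burden from COSMIC-style catalogs, verifies coding-substitution syntax
    against coding sequences, builds confidence-filtered PPI networks
    (kept edges are supported by at least two publications or two detection
    methods), overlays per-sample mutation co-occurrence, aggregates
    per-criterion gene rankings into a Q score by uniform order statistics,
    and applies a guilt-by-association candidate filter. Ships a seeded
    synthetic-data generator with planted, recoverable structure so the whole
    pipeline is testable offline, plus SIF and GraphML exporters readable by
    Cytoscape.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    generics,
    ggplot2,
    igraph,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
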