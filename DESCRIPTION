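Package: mirnatime
Title: Temporal miRNA-mRNA Integration for Tag-Count Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrated temporal analysis of miRNA and mRNA expression across
    developmental time courses sampled without replicates, as in two-breed
    pig skeletal muscle designs. Implements the Audic-Claverie exact
    conditional test for tag-count differential expression with rank-based
    FDR, stage-group DE cataloguing with PCA ordination and hypergeometric
    enrichment, seed-based (nucleotides 2-8) miRNA target prediction over
    3'-UTRs, STEM-style short time-series model-profile clustering with
    permutation significance, and assembly of miRNA-gene interaction
    networks from offline interaction-score tables. A synthetic-data module
    generates tag-count libraries, FPKM time courses, UTR sequences and
    interaction tables with known ground truth so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
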