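Package: litnet
Title: Literature Co-Occurrence Mining and Pathway Network Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Offline two-tier keyword search over annotated abstract
    corpora, hypergeometric and mutual-information scoring of bio-entity
    associations (pairs and triads), assembly of protein interaction and
    pathway meta-networks with crosstalk detection and expression overlay,
    co-authorship and country publication analytics, an NER evaluation
    harness, and a deterministic synthetic-corpus generator for end-to-end
    testing without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
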