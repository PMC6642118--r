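Package: litmesh
Title: Literature-Driven MeSH Prioritisation and Expression Data Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates biomedical literature records with gene expression
    series. Parses the MeSH controlled vocabulary as a multi-placement
    forest and answers structural queries (depth, lowest common ancestor,
    shortest path); prioritises the MeSH annotations of a publication
    corpus by fusing three criteria (hierarchical specificity, corpus
    abundance, global rarity) with Robust Rank Aggregation; scores MeSH
    term and term-set similarity with six tree- and information-content
    based measures normalised to [0,1]; ingests GEO-style series-matrix
    files into a phenotype/expression/platform triplet, collapses probes
    to genes and stratifies samples into cancer and normal groups; and
    runs the downstream analyses (principal components, most-variable-gene
    z-scores with sample clustering, and a co-citation gene network
    overlapped on a scored interactome). A seeded synthetic-fixture
    generator emulates all inputs so the full pipeline runs offline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
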