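Package: bgcrank
Title: Section-Level Ranking of Genome-Mining Predictions by Directed
    PageRank Centrality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aggregates per-genome natural-product prediction counts
    (biosynthetic backbone enzymes, putative metabolite hits with a percent
    sequence match, predicted antimicrobial peptides with keyword
    annotations) into per-section averages, builds a weighted directed
    bipartite section-to-feature graph, and ranks sections and feature
    categories by node strength and by min-max-normalized broadcasting and
    receiving PageRank. Includes a synthetic-data generator with planted
    section-specific Poisson enrichment so the whole pipeline is testable
    without genome downloads, plus readers and writers for a small canonical
    TSV dialect for taxonomy, count and hit tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
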