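Package: ginet
Title: Integration of Signaling and Metabolic Pathways into Global Integrative Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts KEGG-style pathway files (KGML) into a uniform directed
    graph representation in which every metabolic reaction and signaling
    relation is expanded through an intermediate node, so that enzymes,
    substrates, products, protein complexes and signaling effectors all live
    in one connected "meta-pathway" graph. Meta-pathways from many pathway
    files are merged into a species-level global integrative network (GIN)
    with de-duplicated, provenance-tracked edges. On top of the GIN the
    package provides weakly-connected sub-network labeling, cross-species
    sub-network comparison via Jaccard scores over KEGG-orthology-mapped
    genes and compounds, and directed shortest-path crosstalk analysis
    between the member sets of two pathways, with curated edge removal and
    distance-based path weighting. A deterministic synthetic KGML generator
    supports fully offline testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
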