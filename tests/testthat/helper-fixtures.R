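# Hand-written KGML snippets and random-object builders used across tests.

kgml_minimal <- '<?xml version="1.0" encoding="UTF-8"?>
<pathway name="path:syn00010" org="syn" title="minimal">
  <entry id="1" name="syn:0001" type="gene" reaction="rn:R1"/>
  <entry id="2" name="cpd:C90001" type="compound"/>
  <entry id="3" name="cpd:C90002" type="compound"/>
  <reaction id="1" name="rn:R1" type="irreversible">
    <substrate id="2" name="cpd:C90001"/>
    <product id="3" name="cpd:C90002"/>
  </reaction>
</pathway>'

kgml_group <- '<?xml version="1.0" encoding="UTF-8"?>
<pathway name="path:syn00011" org="syn" title="group">
  <entry id="1" name="syn:0001" type="gene"/>
  <entry id="2" name="syn:0002 syn:0003" type="gene"/>
  <entry id="3" name="undefined" type="group">
    <component id="1"/>
    <component id="2"/>
  </entry>
</pathway>'

kgml_dangling <- '<?xml version="1.0" encoding="UTF-8"?>
<pathway name="path:syn00012" org="syn" title="dangling">
  <entry id="1" name="syn:0001" type="gene" reaction="rn:R1"/>
  <entry id="2" name="cpd:C90001" type="compound"/>
  <reaction id="1" name="rn:R1" type="irreversible">
    <substrate id="2" name="cpd:C90001"/>
    <product id="99" name="cpd:C90099"/>
  </reaction>
</pathway>'

# a meta-pathway with random edges over a small node alphabet; wraps the
# edges through merge_metapathways to normalize, then unwraps
random_metapathway <- function(pathway_id, n_edges = 20L,
                               nodes = sprintf("syn:%04d", 1:12)) {
  src <- sample(nodes, n_edges, replace = TRUE)
  tgt <- sample(nodes, n_edges, replace = TRUE)
  edges <- meta_edges(src, tgt,
                      edge_type = sample(1:4, n_edges, replace = TRUE),
                      sign = sample(c("neutral", "activation", "inhibition"),
                                    n_edges, replace = TRUE),
                      pathway_id = pathway_id)
  structure(list(pathway_id = pathway_id, edges = ginet:::dedup_edges(edges)),
            class = "meta_pathway")
}

random_gin <- function(n_nodes = 30L, n_edges = 60L, species = "syn") {
  nodes <- sprintf("syn:%04d", seq_len(n_nodes))
  mp <- random_metapathway(paste0(species, "00001"), n_edges, nodes)
  merge_metapathways(list(mp), species_code = species)
}

gin_equal <- function(a, b) {
  identical(a$species_code, b$species_code) &&
    isTRUE(all.equal(a$edges, b$edges, check.attributes = FALSE))
}
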