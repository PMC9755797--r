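test_that("intermediate ids are canonical and enzyme-sensitive", {
  expect_equal(intermediate_id("F", "C"), "ITM[F|C]")
  expect_equal(intermediate_id("F"), "ITM[F|]")
  # identical substrates under different enzymes stay distinct
  expect_false(intermediate_id("S", "E1") == intermediate_id("S", "E2"))
  # substrate order does not matter
  expect_equal(intermediate_id(c("b", "a"), "E"), intermediate_id(c("a", "b"), "E"))
  expect_error(intermediate_id(character(0)), "substrate")
  p <- intermediate_parts("ITM[cpd:C1;syn:9|CPLX[a+b]]")
  expect_equal(p$substrates, c("cpd:C1", "syn:9"))
  expect_equal(p$enzyme, "CPLX[a+b]")
})

test_that("node classes are decidable from the identifier", {
  expect_equal(node_class(c("hsa:5315", "cpd:C00022", "CPLX[a+b]",
                            "ITM[cpd:C00074|hsa:5315]", "gl:G00001")),
               c("gene", "compound", "complex", "intermediate", "compound"))
})

make_doc <- function(xml) parse_kgml(xml)

test_that("an irreversible catalyzed reaction yields the t2/t3/t4 triplet", {
  doc <- make_doc(kgml_minimal)
  edges <- convert_reaction(doc$reactions[1, ], doc)
  itm <- intermediate_id("cpd:C90001", "syn:0001")
  expect_equal(nrow(edges), 3L)
  expect_true(any(edges$source == "syn:0001" & edges$target == itm &
                    edges$edge_type == 2L))
  expect_true(any(edges$source == "cpd:C90001" & edges$target == itm &
                    edges$edge_type == 3L))
  expect_true(any(edges$source == itm & edges$target == "cpd:C90002" &
                    edges$edge_type == 4L))
  expect_true(all(edges$sign == "neutral"))
})

test_that("reversible reactions split into two opposed intermediates", {
  xml <- sub("irreversible", "reversible", kgml_minimal)
  doc <- make_doc(xml)
  edges <- convert_reaction(doc$reactions[1, ], doc)
  expect_equal(nrow(edges), 6L)
  itms <- unique(grep("^ITM\\[", c(edges$source, edges$target), value = TRUE))
  expect_setequal(itms, c(intermediate_id("cpd:C90001", "syn:0001"),
                          intermediate_id("cpd:C90002", "syn:0001")))
})

test_that("isoenzymes get their own intermediates", {
  xml <- sub('name="syn:0001"', 'name="syn:0001 syn:0002"', kgml_minimal)
  doc <- make_doc(xml)
  edges <- convert_reaction(doc$reactions[1, ], doc)
  # 2 units x (t2 + t3 + t4) = 6 edges over 2 distinct intermediates
  expect_equal(nrow(edges), 6L)
  itms <- unique(edges$target[edges$edge_type == 2L])
  expect_length(itms, 2L)
})

test_that("uncatalyzed reactions form an intermediate with empty enzyme slot", {
  xml <- sub(' reaction="rn:R1"', "", kgml_minimal)
  doc <- make_doc(xml)
  edges <- convert_reaction(doc$reactions[1, ], doc)
  expect_equal(nrow(edges), 2L)  # t3 + t4, no enzyme edge
  expect_true(intermediate_id("cpd:C90001") %in% edges$target)
})

test_that("signaling relations convert with the sign on the effector edge", {
  spec <- fixture_spec(seed = 3, n_reactions = 0L, n_relations = 0L)
  doc <- parse_kgml(generate_kgml(spec))
  # fig1c motif: A activates B, B activates C
  rel <- doc$relations[1, ]
  edges <- convert_relation(rel, doc)
  u <- "syn:8001"; v <- "syn:8002"
  itm <- intermediate_id(v, u)
  expect_equal(nrow(edges), 3L)
  t2 <- edges[edges$edge_type == 2L, ]
  expect_equal(t2$source, u)
  expect_equal(t2$target, itm)
  expect_equal(t2$sign, "activation")
  expect_true(all(edges$sign[edges$edge_type != 2L] == "neutral"))
  # substrate equals product: the t4 edge returns to the downstream node
  expect_true(any(edges$source == itm & edges$target == v &
                    edges$edge_type == 4L))
})

test_that("inhibition subtypes and unsigned subtypes map as documented", {
  b <- ginet:::doc_builder("syn00020", "syn")
  g1 <- ginet:::add_entry(b, "gene", "syn:0001")
  g2 <- ginet:::add_entry(b, "gene", "syn:0002")
  ginet:::add_relation(b, g1, g2, "PPrel", "inhibition")
  ginet:::add_relation(b, g2, g1, "PPrel", "binding/association")
  doc <- ginet:::build_doc(b)
  e1 <- convert_relation(doc$relations[1, ], doc)
  expect_equal(e1$sign[e1$edge_type == 2L], "inhibition")
  e2 <- convert_relation(doc$relations[2, ], doc)
  expect_true(all(e2$sign == "neutral"))
  expect_error(convert_relation(list(rel_type = "other",
                                     rel_type_raw = "ECrel"), doc), "PPrel")
})

test_that("meta-pathway invariants hold on generated fixtures", {
  for (seed in 1:4) {
    spec <- fixture_spec(seed = seed, n_reactions = 6L, n_relations = 8L,
                         p_group = 0.5, p_isoenzyme = 0.5, p_reversible = 0.5)
    doc <- parse_kgml(generate_kgml(spec))
    mp <- build_metapathway(doc)
    e <- mp$edges
    # no duplicate edges
    key <- paste(e$source, e$target, e$edge_type, e$sign)
    expect_equal(anyDuplicated(key), 0L)
    # every intermediate has >= 1 incoming t3 and >= 1 outgoing t4
    itms <- grep("^ITM\\[", graph_nodes(mp), value = TRUE)
    for (itm in itms) {
      expect_true(any(e$target == itm & e$edge_type == 3L))
      expect_true(any(e$source == itm & e$edge_type == 4L))
    }
    # intermediates never source t1-t3 nor receive t4
    from_itm <- startsWith(e$source, "ITM[")
    expect_true(all(e$edge_type[from_itm] == 4L))
    expect_true(all(e$edge_type[startsWith(e$target, "ITM[")] != 4L))
    # no enzyme-release edges: nothing flows intermediate -> its own enzyme
    for (itm in itms) {
      enz <- intermediate_parts(itm)$enzyme
      if (nzchar(enz)) {
        expect_false(any(e$source == itm & e$target == enz))
      }
    }
  }
})

test_that("meta-pathway construction is deterministic", {
  spec <- fixture_spec(seed = 9)
  mp1 <- build_metapathway(parse_kgml(generate_kgml(spec)))
  mp2 <- build_metapathway(parse_kgml(generate_kgml(spec)))
  expect_identical(mp1, mp2)
})

test_that("map entries are excluded from the graph unless requested", {
  xml <- sub('<entry id="3" name="cpd:C90002" type="compound"/>',
             '<entry id="3" name="cpd:C90002" type="compound"/>
  <entry id="4" name="path:syn00099" type="map"/>
  <entry id="5" name="syn:0005" type="gene"/>',
             kgml_minimal)
  xml <- sub("</pathway>",
             '<relation entry1="4" entry2="5" type="PPrel">
  <subtype name="activation" value="-"/></relation></pathway>', xml)
  doc <- parse_kgml(xml)
  mp <- build_metapathway(doc)
  expect_false(any(grepl("path:syn00099", graph_nodes(mp), fixed = TRUE)))
  mp_inc <- build_metapathway(doc, include_map_entries = TRUE)
  expect_true(any(grepl("path:syn00099", graph_nodes(mp_inc), fixed = TRUE)))
})
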