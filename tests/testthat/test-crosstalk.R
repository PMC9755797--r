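test_that("path weight follows the inverse-square node-count rule", {
  expect_equal(edge_weight(2), 1)
  expect_equal(edge_weight(4), 0.25)
  expect_equal(edge_weight(8), 0.0625)
  n <- 2:12
  w <- edge_weight(n)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w <= 1))
  expect_error(edge_weight(1), "at least 2")
})

test_that("pathway members are the gene and compound nodes of the file", {
  doc <- parse_kgml(kgml_minimal)
  expect_equal(pathway_members(doc),
               c("cpd:C90001", "cpd:C90002", "syn:0001"))
  # groups contribute their constituent genes, not the complex node
  doc_g <- parse_kgml(kgml_group)
  expect_equal(pathway_members(doc_g),
               c("syn:0001", "syn:0002", "syn:0003"))
  empty <- parse_kgml('<pathway name="path:syn00099" org="syn"/>')
  expect_equal(pathway_members(empty), character(0))
})

test_that("adjacent members are at node-count distance 2", {
  mp <- structure(list(pathway_id = "syn00001",
                       edges = meta_edges("syn:0001", "syn:0002", 2L,
                                          pathway_id = "syn00001")),
                  class = "meta_pathway")
  gin <- merge_metapathways(list(mp))
  res <- shortest_paths_between(gin, "syn:0001", "syn:0002")
  ab <- res$pairs[res$pairs$direction == "a_to_b", ]
  expect_equal(ab$distance, 2)
  expect_equal(ab$path[[1]], c("syn:0001", "syn:0002"))
  expect_equal(res$retained$a_to_b$weight, 1)
  # the reverse direction is unreachable
  expect_equal(res$pairs$distance[res$pairs$direction == "b_to_a"], Inf)
  expect_null(res$retained$b_to_a)
})

test_that("BFS distances equal the Floyd-Warshall oracle on random GINs", {
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(c(30L, 60L, 120L, 200L), 1)
    gin <- random_gin(n_nodes = n, n_edges = sample(c(n, 2L * n), 1))
    nodes <- graph_nodes(gin)
    fw <- oracle_floyd_warshall(nodes, gin$edges)
    a <- sample(nodes, min(5L, length(nodes) %/% 2))
    b <- sample(setdiff(nodes, a), min(5L, length(nodes) %/% 2))
    res <- shortest_paths_between(gin, a, b, paths = "retained")
    for (k in seq_len(nrow(res$pairs))) {
      row <- res$pairs[k, ]
      expected <- if (row$direction == "a_to_b") {
        fw[row$node_a, row$node_b]
      } else {
        fw[row$node_b, row$node_a]
      }
      expect_equal(row$distance, expected + 1)
    }
    # retained path length is the minimum over its direction
    for (dir in c("a_to_b", "b_to_a")) {
      r <- res$retained[[dir]]
      dd <- res$pairs$distance[res$pairs$direction == dir]
      if (!is.null(r)) {
        expect_equal(r$distance, min(dd))
        expect_equal(length(r$path), r$distance)
      } else {
        expect_true(all(!is.finite(dd)) || length(dd) == 0L)
      }
    }
  }
})

test_that("equal-length ties retain the lexicographically smallest path", {
  # two parallel 3-node routes a -> m1/m2 -> b
  edges <- rbind(meta_edges("a", c("m1", "m2"), 2L, pathway_id = "syn00001"),
                 meta_edges(c("m1", "m2"), "b", 2L, pathway_id = "syn00001"))
  gin <- merge_metapathways(list(structure(
    list(pathway_id = "syn00001", edges = edges), class = "meta_pathway")))
  res <- shortest_paths_between(gin, "a", "b")
  expect_equal(res$retained$a_to_b$path, c("a", "m1", "b"))
})

test_that("shared members are excluded from endpoint sets and reported", {
  pair <- generate_crosstalk_pair(seed = 3)
  gin <- merge_metapathways(list(build_metapathway(pair$doc_a),
                                 build_metapathway(pair$doc_b)))
  res <- shortest_paths_between(gin, pathway_members(pair$doc_a),
                                pathway_members(pair$doc_b))
  expect_setequal(res$shared_excluded, pair$manifest$shared_members)
  endpoint_nodes <- unique(c(res$pairs$node_a, res$pairs$node_b))
  expect_false(any(endpoint_nodes %in% res$shared_excluded))
  expect_false(any(grepl("^ITM\\[", endpoint_nodes)))
})

test_that("planted crosstalk bridges are recovered with their weights", {
  pair <- generate_crosstalk_pair(seed = 4)
  gin <- merge_metapathways(list(build_metapathway(pair$doc_a),
                                 build_metapathway(pair$doc_b)))
  res <- shortest_paths_between(gin, pathway_members(pair$doc_a),
                                pathway_members(pair$doc_b))
  for (dir in c("a_to_b", "b_to_a")) {
    want <- pair$manifest$retained[[dir]]
    got <- res$retained[[dir]]
    expect_equal(got$path, want$path)
    expect_equal(got$distance, want$distance)
    expect_equal(got$weight, want$weight)
    expect_equal(got$weight, edge_weight(got$distance))
  }
  # the longer alternative out-route exists but loses to the 5-node bridge
  relay_row <- res$pairs[res$pairs$direction == "a_to_b" &
                           res$pairs$node_b == "syn:9201", ]
  expect_true(any(is.finite(relay_row$distance)))
})

test_that("curation removes the artifact triplet and disconnects the pair", {
  pair <- generate_crosstalk_pair(seed = 5)
  gin <- merge_metapathways(list(build_metapathway(pair$doc_a),
                                 build_metapathway(pair$doc_b)))
  art <- pair$manifest$artifact
  members_a <- pathway_members(pair$doc_a)
  members_b <- pathway_members(pair$doc_b)
  res_before <- shortest_paths_between(gin, members_a, members_b,
                                       paths = "retained")
  row <- res_before$pairs[res_before$pairs$node_a == art$affected_pair[[1]] &
                            res_before$pairs$node_b == art$affected_pair[[2]] &
                            res_before$pairs$direction == "a_to_b", ]
  expect_equal(row$distance, art$distance_before)

  expect_message(cur <- apply_curation(gin, pair$curation), "removed")
  itm_art <- intermediate_id(art$target, art$source)
  expect_false(itm_art %in% graph_nodes(cur))
  res_after <- shortest_paths_between(cur, members_a, members_b,
                                      paths = "retained")
  # the artifact receptor had no other edges: it drops out of the GIN
  # entirely, so the pair cannot be connected any more
  row2 <- res_after$pairs[res_after$pairs$node_a == art$affected_pair[[1]] &
                            res_after$pairs$node_b == art$affected_pair[[2]] &
                            res_after$pairs$direction == "a_to_b", ]
  expect_true(nrow(row2) == 0L || !is.finite(row2$distance))
  expect_true(art$target %in% res_after$missing ||
                (nrow(row2) == 1L && !is.finite(row2$distance)))
  # curation never shortens any distance (monotonicity)
  key <- function(p) paste(p$node_a, p$node_b, p$direction)
  m <- match(key(res_after$pairs), key(res_before$pairs))
  expect_true(all(res_after$pairs$distance >= res_before$pairs$distance[m]))
  # the genuine bridges survive curation
  expect_equal(res_after$retained$a_to_b$distance, 5)
  expect_equal(res_after$retained$b_to_a$distance, 5)
})

test_that("curation config handles wildcards, no-ops and YAML round trip", {
  gin <- random_gin(n_nodes = 10L, n_edges = 20L)
  expect_true(gin_equal(apply_curation(gin, NULL), gin))
  expect_warning(apply_curation(gin, data.frame(source = "nope",
                                                target = "nope")),
                 "matched no edges")
  src <- gin$edges$source[[1]]
  suppressMessages(cur <- apply_curation(
    gin, data.frame(source = src, target = "*")))
  expect_false(any(cur$edges$source == src))
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(list(source = "a", target = "b", reason = "r")), path)
  tab <- read_curation(path)
  expect_equal(tab$source, "a")
  expect_equal(tab$reason, "r")
})

test_that("bipartite table lists reachable pairs with weights", {
  pair <- generate_crosstalk_pair(seed = 6)
  gin <- merge_metapathways(list(build_metapathway(pair$doc_a),
                                 build_metapathway(pair$doc_b)))
  res <- shortest_paths_between(gin, pathway_members(pair$doc_a),
                                pathway_members(pair$doc_b),
                                paths = "retained")
  tab <- bipartite_table(res)
  expect_true(all(is.finite(tab$distance)))
  expect_equal(tab$weight, edge_weight(tab$distance))
  expect_true(all(tab$direction %in% c("a_to_b", "b_to_a")))
  expect_false(any(grepl("^ITM\\[", c(tab$node_a, tab$node_b))))
  # a GIN with no connection between the sets yields an empty table
  iso <- merge_metapathways(list(structure(list(
    pathway_id = "syn00001",
    edges = meta_edges(c("x1", "y1"), c("x2", "y2"), 2L,
                       pathway_id = "syn00001")), class = "meta_pathway")))
  res0 <- shortest_paths_between(iso, c("x1", "x2"), c("y1", "y2"))
  expect_equal(nrow(bipartite_table(res0)), 0L)
})
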