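# Pathway-pathway crosstalk analysis.
#
# Given a GIN and the member sets of two pathways, crosstalk is quantified
# by directed shortest paths between every ordered pair of members, in both
# directions. Path length is counted in NODES (an adjacent pair has
# n = 2), and each connection is weighted W = (2 / n_shortest)^2, which is
# 1 for a direct connection and suppresses long detours quadratically.
# Activation/inhibition signs do not restrict traversal — an inhibitory
# kinase edge is still a path — they are annotation on the result.
#
# KGML occasionally encodes ambiguous links (e.g. an extracellular ligand
# drawn onto the wrong receptor) that would fabricate crosstalk; a curation
# list of (source, target) removals is applied to the GIN first, deleting
# both direct edges and the intermediate triplets derived from the curated
# relation.

#' Read a curation list
#'
#' @param path YAML file: a list of records with keys `source`, `target`
#'   and optional `reason`. `"*"` is a wildcard matching any node.
#' @return data frame with columns `source`, `target`, `reason`.
#' @export
read_curation <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) {
    return(data.frame(source = character(0), target = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    source = vapply(raw, function(r) as.character(r$source), character(1)),
    target = vapply(raw, function(r) as.character(r$target), character(1)),
    reason = vapply(raw, function(r) {
      if (is.null(r$reason)) "" else as.character(r$reason)
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

match_node <- function(pattern, values) {
  if (pattern == "*") rep(TRUE, length(values)) else values == pattern
}

#' Apply curated edge removals to a GIN
#'
#' Each removal `(source, target)` deletes (a) direct edges whose endpoints
#' match, and (b) the whole intermediate triplet derived from the curated
#' relation: every edge incident to an intermediate whose enzyme slot
#' matches `source` and whose substrate set contains a match of `target`.
#' Patterns are exact node ids or the wildcard `"*"`. A removal that
#' matches nothing raises a warning, not an error; the number of edges
#' removed per rule is reported via `message()`.
#'
#' @param gin a `gin`.
#' @param curation data frame with columns `source`, `target` and
#'   optionally `reason` (see [read_curation()]).
#' @return the curated `gin`.
#' @export
apply_curation <- function(gin, curation) {
  stopifnot(inherits(gin, "gin"))
  if (is.null(curation) || !nrow(curation)) return(gin)
  edges <- gin$edges
  nodes <- graph_nodes(gin)
  itm_nodes <- nodes[startsWith(nodes, "ITM[")]
  itm_parts <- lapply(itm_nodes, intermediate_parts)
  for (i in seq_len(nrow(curation))) {
    src <- curation$source[[i]]
    tgt <- curation$target[[i]]
    drop <- match_node(src, edges$source) & match_node(tgt, edges$target)
    hit_itm <- itm_nodes[vapply(itm_parts, function(p) {
      nzchar(p$enzyme) && any(match_node(src, p$enzyme)) &&
        any(match_node(tgt, p$substrates))
    }, logical(1))]
    if (length(hit_itm)) {
      drop <- drop | edges$source %in% hit_itm | edges$target %in% hit_itm
    }
    n_drop <- sum(drop)
    if (n_drop == 0L) {
      warning("curation rule (", src, " -> ", tgt, ") matched no edges",
              call. = FALSE)
    } else {
      message("curation rule (", src, " -> ", tgt, ") removed ", n_drop,
              " edge(s)")
      edges <- edges[!drop, , drop = FALSE]
    }
  }
  rownames(edges) <- NULL
  new_gin(edges, gin$species_code)
}

#' Member nodes of a pathway
#'
#' The gene and compound node ids a pathway contributes: the names of its
#' gene, enzyme and compound entries plus the constituent genes of its
#' group entries. Intermediates and complex nodes are GIN constructs, not
#' members.
#'
#' @param doc a `pathway_doc`.
#' @param include_map_entries also take names of `map`/`ortholog` entries.
#' @return sorted character vector of node ids.
#' @export
pathway_members <- function(doc, include_map_entries = FALSE) {
  stopifnot(inherits(doc, "pathway_doc"))
  keep <- c("gene", "compound", "enzyme", "group")
  if (include_map_entries) keep <- c(keep, "map", "ortholog")
  members <- character(0)
  for (i in seq_len(nrow(doc$entries))) {
    type <- doc$entries$entry_type[[i]]
    if (!type %in% keep) next
    if (type == "group") {
      units <- entry_units(doc, doc$entries$entry_id[[i]])
      members <- c(members, unlist(lapply(units, unit_members)))
    } else {
      members <- c(members, doc$entries$names[[i]])
    }
  }
  sort(unique(members))
}

# lexicographically smallest shortest path from `from` to `to`, given the
# vector of distances (edge counts) of every vertex to `to`; greedy choice
# of the smallest-named admissible successor is lexicographically minimal
# because all admissible continuations have equal length
lex_shortest_path <- function(g, from, to, dist_to) {
  path <- from
  cur <- from
  d <- dist_to[[from]]
  while (cur != to) {
    succ <- names(igraph::neighbors(g, cur, mode = "out"))
    succ <- succ[dist_to[succ] == d - 1]
    cur <- min(succ)
    path <- c(path, cur)
    d <- d - 1
  }
  path
}

#' Directed shortest paths between two pathway member sets
#'
#' Treats the GIN as an unweighted directed graph and computes, for every
#' ordered pair (a in A, b in B) and both directions, the breadth-first
#' shortest-path distance in node counts (adjacent nodes: 2; unreachable:
#' `Inf`). Nodes belonging to both member sets are excluded from the
#' endpoint sets and reported, as are members absent from the GIN. In each
#' direction the single extreme shortest path is retained; ties (equal
#' node count) are broken by the lexicographically smallest node sequence.
#'
#' @param gin a `gin` (curated, typically; see [apply_curation()]).
#' @param set_a,set_b character vectors of member node ids (see
#'   [pathway_members()]).
#' @param paths `"all"` materializes the path node sequence of every
#'   reachable pair; `"retained"` only for the two extreme paths.
#' @return a `crosstalk_result`: list with `pairs` (data frame `node_a`,
#'   `node_b`, `direction`, `distance`, list column `path`), `retained`
#'   (per direction: `path`, `distance`, `weight`), `shared_excluded`,
#'   `missing`.
#' @export
shortest_paths_between <- function(gin, set_a, set_b,
                                   paths = c("all", "retained")) {
  stopifnot(inherits(gin, "gin"))
  paths <- match.arg(paths)
  nodes <- graph_nodes(gin)
  set_a <- sort(unique(as.character(set_a)))
  set_b <- sort(unique(as.character(set_b)))
  shared <- intersect(set_a, set_b)
  missing <- sort(setdiff(union(set_a, set_b), nodes))
  a <- setdiff(intersect(set_a, nodes), shared)
  b <- setdiff(intersect(set_b, nodes), shared)

  g <- gin_igraph(gin)
  empty_pairs <- data.frame(node_a = character(0), node_b = character(0),
                            direction = character(0), distance = numeric(0),
                            stringsAsFactors = FALSE)
  empty_pairs$path <- list()
  result <- list(pairs = empty_pairs,
                 retained = list(a_to_b = NULL, b_to_a = NULL),
                 shared_excluded = shared, missing = missing)
  class(result) <- "crosstalk_result"
  if (!length(a) || !length(b)) return(result)

  # edge-count distance matrices for both directions; node count = d + 1
  d_ab <- igraph::distances(g, v = a, to = b, mode = "out")
  d_ba <- igraph::distances(g, v = b, to = a, mode = "out")

  # per-target distance vectors, for lexicographic path reconstruction
  dist_to <- new.env(parent = emptyenv())
  get_dist_to <- function(target) {
    if (is.null(dist_to[[target]])) {
      dist_to[[target]] <- igraph::distances(g, to = target, mode = "out")[, 1L]
    }
    dist_to[[target]]
  }

  rows <- list()
  retained <- list(a_to_b = NULL, b_to_a = NULL)
  for (dir in c("a_to_b", "b_to_a")) {
    dm <- if (dir == "a_to_b") d_ab else d_ba
    from_set <- rownames(dm)
    to_set <- colnames(dm)
    best <- NULL
    for (fi in seq_along(from_set)) {
      for (ti in seq_along(to_set)) {
        d_edges <- dm[fi, ti]
        n_nodes <- d_edges + 1
        pth <- NULL
        if (is.finite(d_edges) && paths == "all") {
          pth <- lex_shortest_path(g, from_set[[fi]], to_set[[ti]],
                                   get_dist_to(to_set[[ti]]))
        }
        rows[[length(rows) + 1L]] <- list(
          node_a = if (dir == "a_to_b") from_set[[fi]] else to_set[[ti]],
          node_b = if (dir == "a_to_b") to_set[[ti]] else from_set[[fi]],
          direction = dir, distance = n_nodes, path = pth)
        if (is.finite(d_edges) &&
            (is.null(best) || n_nodes < best$distance)) {
          best <- list(from = from_set[[fi]], to = to_set[[ti]],
                       distance = n_nodes)
        }
      }
    }
    if (!is.null(best)) {
      # collect all pairs at the minimal distance, break ties by path
      cand <- which(dm == best$distance - 1, arr.ind = TRUE)
      cand_paths <- lapply(seq_len(nrow(cand)), function(k) {
        to <- to_set[[cand[k, 2L]]]
        lex_shortest_path(g, from_set[[cand[k, 1L]]], to, get_dist_to(to))
      })
      keys <- vapply(cand_paths, paste, character(1), collapse = "\\r")
      pick <- order(keys)[[1L]]
      retained[[dir]] <- list(path = cand_paths[[pick]],
                              distance = best$distance,
                              weight = edge_weight(best$distance))
    }
  }
  pairs <- data.frame(
    node_a = vapply(rows, `[[`, character(1), "node_a"),
    node_b = vapply(rows, `[[`, character(1), "node_b"),
    direction = vapply(rows, `[[`, character(1), "direction"),
    distance = vapply(rows, `[[`, numeric(1), "distance"),
    stringsAsFactors = FALSE
  )
  pairs$path <- lapply(rows, `[[`, "path")
  ord <- order(pairs$direction, pairs$node_a, pairs$node_b)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  result$pairs <- pairs
  result$retained <- retained
  result
}

#' Crosstalk path weight
#'
#' `W = (2 / n_shortest)^2` where `n_shortest` is the number of nodes on
#' the shortest path. Adjacent nodes (`n = 2`) get the maximal weight 1;
#' the square suppresses long paths.
#'
#' @param n_shortest node count(s) of shortest path(s), each >= 2.
#' @return numeric weight(s) in `(0, 1]`.
#' @export
edge_weight <- function(n_shortest) {
  if (any(n_shortest < 2)) {
    stop("a path between distinct nodes has at least 2 nodes", call. = FALSE)
  }
  (2 / n_shortest)^2
}

#' Weighted bipartite connection table
#'
#' One row per reachable ordered member pair: endpoints (never
#' intermediates), direction, node-count distance and weight
#' `W = (2/n)^2`. This is the table behind a bipartite layout in which
#' line width encodes closeness and color the direction.
#'
#' @param result a `crosstalk_result`.
#' @return data frame with columns `node_a`, `node_b`, `direction`,
#'   `distance`, `weight`.
#' @export
bipartite_table <- function(result) {
  stopifnot(inherits(result, "crosstalk_result"))
  p <- result$pairs
  p <- p[is.finite(p$distance), , drop = FALSE]
  out <- data.frame(node_a = p$node_a, node_b = p$node_b,
                    direction = p$direction, distance = p$distance,
                    weight = if (nrow(p)) edge_weight(p$distance) else numeric(0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.crosstalk_result <- function(x, ...) {
  reach <- sum(is.finite(x$pairs$distance))
  cat("<crosstalk_result> ", nrow(x$pairs), " ordered pairs, ", reach,
      " reachable\n", sep = "")
  for (dir in c("a_to_b", "b_to_a")) {
    r <- x$retained[[dir]]
    if (is.null(r)) {
      cat("  ", dir, ": no path\n", sep = "")
    } else {
      cat("  ", dir, ": n=", r$distance, " W=", signif(r$weight, 4), "  ",
          paste(r$path, collapse = " -> "), "\n", sep = "")
    }
  }
  if (length(x$shared_excluded)) {
    cat("  shared members excluded: ", length(x$shared_excluded), "\n",
        sep = "")
  }
  invisible(x)
}
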