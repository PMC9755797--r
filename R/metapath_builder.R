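# Meta-pathway construction.
#
# The meta-pathway is a uniform directed-graph encoding of both metabolic
# reactions and signaling relations. Every reaction/relation is split in two
# steps through an introduced intermediate node that uniquely identifies the
# complex of substrate(s) with or without the enzyme. Four edge types result:
#   type 1  subunit      -> protein complex
#   type 2  enzyme unit  -> intermediate
#   type 3  substrate    -> intermediate
#   type 4  intermediate -> product
# The enzyme's landing point on the intermediate (type 2) is what stitches
# signaling cascades and metabolic reactions into one connected graph; the
# reverse "enzyme release" edge (intermediate -> enzyme) is deliberately not
# emitted. Downstream graph algorithms treat all four types alike.

EDGE_SIGNS <- c("activation", "inhibition", "neutral")

# relation subtypes that carry a sign; everything else (binding/association,
# phosphorylation alone, indirect effect, ...) is neutral
ACTIVATING_SUBTYPES <- c("activation", "expression")
INHIBITING_SUBTYPES <- c("inhibition", "repression")

#' Construct a meta-edge table
#'
#' The meta-edge data frame is the package's exchange format for edges:
#' columns `source`, `target`, `edge_type` (1-4), `sign`
#' (activation/inhibition/neutral) and `pathway_id` (provenance). Arguments
#' are recycled to a common length.
#'
#' @export
meta_edges <- function(source, target, edge_type, sign = "neutral",
                       pathway_id = "") {
  out <- data.frame(source = as.character(source),
                    target = as.character(target),
                    edge_type = as.integer(edge_type),
                    sign = as.character(sign),
                    pathway_id = as.character(pathway_id),
                    stringsAsFactors = FALSE)
  bad <- setdiff(unique(out$sign), EDGE_SIGNS)
  if (length(bad)) stop("invalid edge sign: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out
}

empty_meta_edges <- function() {
  data.frame(source = character(0), target = character(0),
             edge_type = integer(0), sign = character(0),
             pathway_id = character(0), stringsAsFactors = FALSE)
}

#' Canonical intermediate node identifier
#'
#' An intermediate is named by its sorted substrate set and its enzyme unit:
#' `ITM[s1;s2|enzyme]`, with an empty enzyme slot for uncatalyzed reactions.
#' Identical substrates under different (iso)enzymes therefore produce
#' distinct intermediates.
#'
#' @param substrates non-empty character vector of substrate node ids.
#' @param enzyme single enzyme unit id, or `NULL`/`NA` for the enzyme-free
#'   case.
#' @return single string.
#' @export
#' @examples
#' intermediate_id("cpd:C90006", "syn:0003")  # "ITM[cpd:C90006|syn:0003]"
intermediate_id <- function(substrates, enzyme = NULL) {
  substrates <- sort(unique(as.character(substrates)))
  if (!length(substrates)) stop("intermediate needs at least one substrate",
                                call. = FALSE)
  enzyme <- if (is.null(enzyme) || is.na(enzyme)) "" else as.character(enzyme)
  paste0("ITM[", paste(substrates, collapse = ";"), "|", enzyme, "]")
}

#' Decompose an intermediate id
#'
#' @param node an `ITM[...]` node id.
#' @return list with `substrates` (character vector) and `enzyme` (string,
#'   `""` when uncatalyzed).
#' @export
intermediate_parts <- function(node) {
  if (!startsWith(node, "ITM[")) stop(node, " is not an intermediate id",
                                      call. = FALSE)
  body <- substr(node, 5L, nchar(node) - 1L)
  # substrate ids contain no "|", so the first "|" separates the two slots
  cut <- regexpr("|", body, fixed = TRUE)
  list(substrates = strsplit(substr(body, 1L, cut - 1L), ";", fixed = TRUE)[[1]],
       enzyme = substr(body, cut + 1L, nchar(body)))
}

#' Classify node identifiers
#'
#' Node classes are decidable from the id alone: `ITM[...]` intermediates,
#' `CPLX[...]` complexes, compound namespaces (`cpd:`, `gl:`, `dr:`), and
#' everything else a gene/protein.
#'
#' @param nodes character vector of node ids.
#' @return character vector in \{gene, compound, complex, intermediate\}.
#' @export
node_class <- function(nodes) {
  ifelse(startsWith(nodes, "ITM["), "intermediate",
  ifelse(startsWith(nodes, "CPLX["), "complex",
  ifelse(grepl("^(cpd|gl|dr):", nodes), "compound", "gene")))
}

relation_sign <- function(subtypes) {
  if (any(subtypes %in% ACTIVATING_SUBTYPES)) "activation"
  else if (any(subtypes %in% INHIBITING_SUBTYPES)) "inhibition"
  else "neutral"
}

# node ids an entry contributes to the graph (units for genes/groups,
# compound ids for compounds)
entry_node_ids <- function(doc, entry_ids) {
  sort(unique(unlist(lapply(entry_ids, function(id) entry_units(doc, id)))))
}

#' Convert one metabolic reaction to meta-edges
#'
#' Emits, per direction (one for irreversible reactions, both for reversible
#' ones, i.e. a reversible reaction is split into two opposed reactions) and
#' per enzyme unit (or once with an empty enzyme slot when uncatalyzed):
#' a type-2 edge enzyme -> intermediate, type-3 edges substrate ->
#' intermediate and type-4 edges intermediate -> product, all neutral.
#' Multi-compound substrate sets share one intermediate. Type-1
#' subunit edges of complex enzyme units are included once.
#'
#' @param reaction one row of `doc$reactions` (a list or single-row data
#'   frame with fields `reaction_id`, `direction`, `substrates`, `products`,
#'   `enzymes`).
#' @param doc the owning `pathway_doc`.
#' @param enzyme_units character vector of enzyme unit ids; defaults to the
#'   units resolved from the reaction's enzyme entries.
#' @return meta-edge data frame.
#' @export
convert_reaction <- function(reaction, doc, enzyme_units = NULL) {
  if (is.data.frame(reaction)) reaction <- as.list(reaction[1, ])
  subs <- entry_node_ids(doc, reaction$substrates[[1]])
  prods <- entry_node_ids(doc, reaction$products[[1]])
  if (!length(subs) || !length(prods)) {
    stop("reaction ", reaction$reaction_id,
         " has unresolvable substrates or products", call. = FALSE)
  }
  if (is.null(enzyme_units)) {
    enzyme_units <- entry_node_ids(doc, reaction$enzymes[[1]])
  }
  directions <- list(list(s = subs, p = prods))
  if (identical(reaction$direction, "reversible")) {
    directions <- c(directions, list(list(s = prods, p = subs)))
  }
  units <- if (length(enzyme_units)) enzyme_units else NA_character_
  out <- list()
  for (dir in directions) {
    for (u in units) {
      itm <- intermediate_id(dir$s, u)
      if (!is.na(u)) {
        out[[length(out) + 1L]] <- meta_edges(u, itm, 2L,
                                              pathway_id = doc$pathway_id)
        out[[length(out) + 1L]] <- complex_edges(u, pathway_id = doc$pathway_id)
      }
      out[[length(out) + 1L]] <- meta_edges(dir$s, itm, 3L,
                                            pathway_id = doc$pathway_id)
      out[[length(out) + 1L]] <- meta_edges(itm, dir$p, 4L,
                                            pathway_id = doc$pathway_id)
    }
  }
  dedup_edges(do.call(rbind, out))
}

#' Convert one signaling relation to meta-edges
#'
#' A PPrel/PCrel relation from upstream U to downstream V is read as a
#' reaction in which U acts as the enzyme and V is both substrate and
#' product (the modification changes only a small chemical group): U ->
#' `ITM[V|U]` (type 2, carrying the relation's activation/inhibition sign),
#' V -> `ITM[V|U]` (type 3) and `ITM[V|U]` -> V (type 4). Group endpoints
#' are resolved to their enzyme units, one triplet per unit pair; type-1
#' subunit edges for complex units are included.
#'
#' @param rel one row of `doc$relations`.
#' @param doc the owning `pathway_doc`.
#' @return meta-edge data frame.
#' @export
convert_relation <- function(rel, doc) {
  if (is.data.frame(rel)) rel <- as.list(rel[1, ])
  if (!rel$rel_type %in% c("PPrel", "PCrel")) {
    stop("convert_relation only accepts PPrel/PCrel relations (got ",
         rel$rel_type_raw, ")", call. = FALSE)
  }
  upstream <- entry_units(doc, rel$entry1)
  downstream <- entry_units(doc, rel$entry2)
  sign <- relation_sign(rel$subtypes[[1]])
  out <- list()
  for (u in upstream) {
    for (v in downstream) {
      itm <- intermediate_id(v, u)
      out[[length(out) + 1L]] <- meta_edges(u, itm, 2L, sign,
                                            pathway_id = doc$pathway_id)
      out[[length(out) + 1L]] <- meta_edges(v, itm, 3L,
                                            pathway_id = doc$pathway_id)
      out[[length(out) + 1L]] <- meta_edges(itm, v, 4L,
                                            pathway_id = doc$pathway_id)
      out[[length(out) + 1L]] <- complex_edges(u, pathway_id = doc$pathway_id)
      out[[length(out) + 1L]] <- complex_edges(v, pathway_id = doc$pathway_id)
    }
  }
  dedup_edges(do.call(rbind, out))
}

# drop duplicate (source, target, edge_type, sign) rows and sort canonically
dedup_edges <- function(edges) {
  if (is.null(edges) || !nrow(edges)) return(empty_meta_edges())
  key <- paste(edges$source, edges$target, edges$edge_type, edges$sign,
               sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges$source, edges$target, edges$edge_type,
                       edges$sign), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Build the meta-pathway of one pathway document
#'
#' Applies [convert_reaction()] to every reaction and [convert_relation()]
#' to every PPrel/PCrel relation, de-duplicates the union and sorts it
#' canonically. Only molecules present in the file take part (cofactors
#' absent from the KGML are not recovered from the reaction equation, so
#' ubiquitous currency metabolites do not short-circuit unrelated
#' pathways). Entries of type `map` and `ortholog` (links to other pathway
#' maps, non-species orthologs) are excluded by default.
#'
#' @param doc a `pathway_doc`.
#' @param include_map_entries include `map`/`ortholog` entries as graph
#'   nodes instead of dropping the reactions/relations that touch them.
#' @return A `meta_pathway` object: list with `pathway_id` and `edges`.
#' @export
build_metapathway <- function(doc, include_map_entries = FALSE) {
  stopifnot(inherits(doc, "pathway_doc"))
  excluded <- integer(0)
  if (!include_map_entries) {
    excluded <- doc$entries$entry_id[doc$entries$entry_type %in%
                                       c("map", "ortholog")]
  }
  out <- list(empty_meta_edges())
  for (i in seq_len(nrow(doc$reactions))) {
    r <- as.list(doc$reactions[i, ])
    r$substrates[[1]] <- setdiff(r$substrates[[1]], excluded)
    r$products[[1]] <- setdiff(r$products[[1]], excluded)
    r$enzymes[[1]] <- setdiff(r$enzymes[[1]], excluded)
    if (!length(r$substrates[[1]]) || !length(r$products[[1]])) next
    out[[length(out) + 1L]] <- convert_reaction(r, doc)
  }
  for (i in seq_len(nrow(doc$relations))) {
    rel <- as.list(doc$relations[i, ])
    if (!rel$rel_type %in% c("PPrel", "PCrel")) next
    if (rel$entry1 %in% excluded || rel$entry2 %in% excluded) next
    out[[length(out) + 1L]] <- convert_relation(rel, doc)
  }
  structure(list(pathway_id = doc$pathway_id,
                 edges = dedup_edges(do.call(rbind, out))),
            class = "meta_pathway")
}

#' Nodes of a meta-pathway or GIN
#'
#' @param x a `meta_pathway` or `gin` object.
#' @return sorted character vector of node ids appearing as an edge
#'   endpoint.
#' @export
graph_nodes <- function(x) {
  sort(unique(c(x$edges$source, x$edges$target)))
}

#' @export
print.meta_pathway <- function(x, ...) {
  nodes <- graph_nodes(x)
  cat("<meta_pathway> ", x$pathway_id, ": ", nrow(x$edges), " edges, ",
      length(nodes), " nodes (", sum(startsWith(nodes, "ITM[")),
      " intermediates)\n", sep = "")
  invisible(x)
}
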