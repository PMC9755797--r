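# Assembly of the species-level global integrative network (GIN).
#
# A GIN is the union of all meta-pathways of one species with redundant
# edges (identical source, target, type and sign arising from overlapping
# pathways) collapsed to a single copy whose provenance records every
# contributing pathway. GINs are read and written as SIF (simple
# interaction file): three tab-separated columns source, relation-label,
# target, the Cytoscape-compatible hand-off format.

species_of <- function(pathway_id) sub("[0-9].*$", "", pathway_id)

new_gin <- function(edges, species_code) {
  structure(list(species_code = species_code, edges = edges), class = "gin")
}

#' Merge meta-pathways into a GIN
#'
#' Union of the edge sets with duplicates collapsed; the provenance of a
#' collapsed edge is the sorted, `;`-joined set of contributing pathway
#' ids. Merging is idempotent, commutative and associative, so the result
#' does not depend on input order.
#'
#' @param paths list of `meta_pathway` objects (a single one is accepted),
#'   all from one species.
#' @param species_code species code; inferred from the pathway ids' alpha
#'   prefix when omitted (mixed prefixes are an error).
#' @return a `gin` object.
#' @export
merge_metapathways <- function(paths, species_code = NULL) {
  if (inherits(paths, "meta_pathway")) paths <- list(paths)
  stopifnot(length(paths) >= 1L,
            all(vapply(paths, inherits, logical(1), "meta_pathway")))
  codes <- unique(vapply(paths, function(p) species_of(p$pathway_id),
                         character(1)))
  if (is.null(species_code)) {
    if (length(codes) > 1L) {
      stop("meta-pathways from mixed species: ",
           paste(codes, collapse = ", "), call. = FALSE)
    }
    species_code <- codes
  }
  edges <- do.call(rbind, lapply(paths, function(p) p$edges))
  if (is.null(edges) || !nrow(edges)) {
    e <- empty_meta_edges()
    names(e)[names(e) == "pathway_id"] <- "pathways"
    return(new_gin(e, species_code))
  }
  key <- paste(edges$source, edges$target, edges$edge_type, edges$sign,
               sep = "\r")
  prov <- vapply(split(edges$pathway_id, key), function(p) {
    paste(sort(unique(unlist(strsplit(p, ";", fixed = TRUE)))), collapse = ";")
  }, character(1))
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges$pathway_id <- NULL
  edges$pathways <- unname(prov[paste(edges$source, edges$target,
                                      edges$edge_type, edges$sign,
                                      sep = "\r")])
  edges <- edges[order(edges$source, edges$target, edges$edge_type,
                       edges$sign), , drop = FALSE]
  rownames(edges) <- NULL
  new_gin(edges, species_code)
}

#' Merge two GINs
#'
#' @param a,b `gin` objects with the same species code.
#' @return merged `gin`.
#' @export
merge_gins <- function(a, b) {
  stopifnot(inherits(a, "gin"), inherits(b, "gin"))
  if (!identical(a$species_code, b$species_code)) {
    stop("cannot merge GINs of different species", call. = FALSE)
  }
  to_mp <- function(g) {
    e <- g$edges
    names(e)[names(e) == "pathways"] <- "pathway_id"
    structure(list(pathway_id = g$species_code, edges = e),
              class = "meta_pathway")
  }
  merge_metapathways(list(to_mp(a), to_mp(b)), species_code = a$species_code)
}

sif_relation_label <- function(edge_type, sign) {
  paste0("t", edge_type, ifelse(sign == "neutral", "", paste0(":", sign)))
}

#' Write a network in SIF format
#'
#' Three tab-separated columns: source node, relation label, target node.
#' The relation label encodes the edge type (`t1`..`t4`) with an optional
#' `:activation`/`:inhibition` suffix. Rows are written in canonical
#' lexicographic order, UTF-8, `\n` line endings, so repeated writes of the
#' same network are byte-identical. For a `gin`, a sidecar
#' `<path>.attrs.tsv` records the species code and each edge's pathway
#' provenance so that [read_sif()] can reconstruct the object exactly.
#'
#' @param x a `gin` or `meta_pathway`.
#' @param path output file path.
#' @param sidecar write the provenance sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_sif <- function(x, path, sidecar = TRUE) {
  UseMethod("write_sif")
}

sif_lines <- function(edges) {
  if (!nrow(edges)) return(character(0))
  paste(edges$source, sif_relation_label(edges$edge_type, edges$sign),
        edges$target, sep = "\t")
}

#' @export
write_sif.gin <- function(x, path, sidecar = TRUE) {
  edges <- dedup_gin_edges(x$edges)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sif_lines(edges), con, sep = "\n", useBytes = TRUE)
  if (sidecar) {
    side <- file(paste0(path, ".attrs.tsv"), open = "wb")
    on.exit(close(side), add = TRUE)
    writeLines(c(paste0("#species=", x$species_code),
                 if (nrow(edges)) paste(edges$source,
                                        sif_relation_label(edges$edge_type,
                                                           edges$sign),
                                        edges$target, edges$pathways,
                                        sep = "\t")),
               side, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' @export
write_sif.meta_pathway <- function(x, path, sidecar = TRUE) {
  edges <- dedup_edges(x$edges)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sif_lines(edges), con, sep = "\n", useBytes = TRUE)
  if (sidecar) {
    side <- file(paste0(path, ".attrs.tsv"), open = "wb")
    on.exit(close(side), add = TRUE)
    writeLines(c(paste0("#pathway=", x$pathway_id),
                 if (nrow(edges)) paste(edges$source,
                                        sif_relation_label(edges$edge_type,
                                                           edges$sign),
                                        edges$target, edges$pathway_id,
                                        sep = "\t")),
               side, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

dedup_gin_edges <- function(edges) {
  key <- paste(edges$source, edges$target, edges$edge_type, edges$sign,
               sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges$source, edges$target, edges$edge_type,
                       edges$sign), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

parse_relation_label <- function(label, path) {
  m <- regmatches(label, regexec("^t([1-4])(?::(activation|inhibition))?$",
                                 label))
  bad <- which(!vapply(m, length, integer(1)))
  if (length(bad)) {
    stop("malformed SIF relation label in ", path, " at data line ",
         bad[[1]], ": '", label[bad[[1]]], "'", call. = FALSE)
  }
  list(edge_type = as.integer(vapply(m, `[[`, character(1), 2L)),
       sign = ifelse(vapply(m, `[[`, character(1), 3L) == "",
                     "neutral", vapply(m, `[[`, character(1), 3L)))
}

#' Read a GIN from a SIF file
#'
#' Reads the three-column SIF written by [write_sif()] and, when present,
#' the `<path>.attrs.tsv` sidecar with the species code and per-edge
#' provenance. Without a sidecar the species code must be supplied and
#' provenance is empty.
#'
#' @param path SIF file path.
#' @param species_code fallback species code when no sidecar exists.
#' @return a `gin`.
#' @export
read_sif <- function(path, species_code = NA_character_) {
  if (!file.exists(path)) stop("SIF file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf != 3L)) {
    stop("malformed SIF line ", which(nf != 3L)[[1]], " in ", path,
         ": expected 3 tab-separated fields", call. = FALSE)
  }
  src <- vapply(parts, `[[`, character(1), 1L)
  lab <- vapply(parts, `[[`, character(1), 2L)
  tgt <- vapply(parts, `[[`, character(1), 3L)
  rel <- if (length(lab)) parse_relation_label(lab, path) else
    list(edge_type = integer(0), sign = character(0))
  edges <- data.frame(source = src, target = tgt,
                      edge_type = rel$edge_type, sign = rel$sign,
                      pathways = rep("", length(src)),
                      stringsAsFactors = FALSE)

  side_path <- paste0(path, ".attrs.tsv")
  if (file.exists(side_path)) {
    side <- readLines(side_path, encoding = "UTF-8")
    header <- side[startsWith(side, "#")]
    sp <- sub("^#species=", "", header[startsWith(header, "#species=")])
    if (length(sp)) species_code <- sp[[1]]
    body <- side[!startsWith(side, "#") & nzchar(side)]
    if (length(body)) {
      sparts <- strsplit(body, "\t", fixed = TRUE)
      skey <- vapply(sparts, function(p) paste(p[1:3], collapse = "\t"),
                     character(1))
      sprov <- vapply(sparts, function(p) if (length(p) >= 4L) p[[4]] else "",
                      character(1))
      hit <- match(paste(src, lab, tgt, sep = "\t"), skey)
      edges$pathways <- ifelse(is.na(hit), "", sprov[hit])
    }
  }
  new_gin(dedup_gin_edges(edges), species_code)
}

gin_igraph <- function(x) {
  nodes <- graph_nodes(x)
  pairs <- unique(x$edges[, c("source", "target")])
  igraph::graph_from_data_frame(pairs, directed = TRUE, vertices = nodes)
}

#' Label the sub-networks of a GIN
#'
#' Computes the weakly-connected components of the directed graph and
#' numbers those with more than `min_size` nodes by decreasing size:
#' subnet 1 is the largest. Ties in size are broken by the
#' lexicographically smallest member node id. Components at or below the
#' size cutoff stay unlabeled.
#'
#' @param gin a `gin`.
#' @param min_size components must exceed this node count to be labeled
#'   (default 10).
#' @return a `subnet_labeling`: list with `assignments` (named integer
#'   vector node -> label over labeled nodes) and `component_sizes` (named
#'   integer vector label -> node count).
#' @export
label_subnets <- function(gin, min_size = 10L) {
  stopifnot(inherits(gin, "gin"))
  nodes <- graph_nodes(gin)
  if (!length(nodes)) {
    return(structure(list(assignments = structure(integer(0), names = character(0)),
                          component_sizes = structure(integer(0), names = character(0))),
                     class = "subnet_labeling"))
  }
  comp <- igraph::components(gin_igraph(gin), mode = "weak")
  membership <- comp$membership[nodes]
  sizes <- comp$csize
  reps <- vapply(seq_along(sizes), function(k) {
    min(nodes[membership == k])
  }, character(1))
  keep <- which(sizes > min_size)
  keep <- keep[order(-sizes[keep], reps[keep])]
  assignments <- integer(0)
  nms <- character(0)
  for (lab in seq_along(keep)) {
    members <- nodes[membership == keep[[lab]]]
    assignments <- c(assignments, rep.int(lab, length(members)))
    nms <- c(nms, members)
  }
  names(assignments) <- nms
  component_sizes <- sizes[keep]
  names(component_sizes) <- as.character(seq_along(keep))
  structure(list(assignments = assignments,
                 component_sizes = component_sizes),
            class = "subnet_labeling")
}

#' @export
print.subnet_labeling <- function(x, ...) {
  cat("<subnet_labeling> ", length(x$component_sizes), " labeled subnets, ",
      length(x$assignments), " labeled nodes\n", sep = "")
  if (length(x$component_sizes)) {
    print(utils::head(x$component_sizes, 10L))
  }
  invisible(x)
}

#' Classify GIN nodes as compound-related or protein-only
#'
#' Compound nodes, and intermediates that contain a compound (among their
#' substrates or in the enzyme slot, as a protein-compound relation puts
#' the compound upstream), are `compound_related`; every other node —
#' genes, complexes, protein-only intermediates — is `protein_only`.
#'
#' @param gin a `gin` (or anything with an `edges` data frame).
#' @return named character vector over the node set.
#' @export
classify_nodes <- function(gin) {
  nodes <- graph_nodes(gin)
  cls <- node_class(nodes)
  out <- ifelse(cls == "compound", "compound_related", "protein_only")
  itm <- which(cls == "intermediate")
  for (i in itm) {
    parts <- intermediate_parts(nodes[[i]])
    inside <- c(parts$substrates,
                if (nzchar(parts$enzyme)) unit_members(parts$enzyme))
    if (any(node_class(inside) == "compound")) out[[i]] <- "compound_related"
  }
  names(out) <- nodes
  out
}

#' Summary statistics of a GIN
#'
#' @param gin a `gin`.
#' @return list with `species_code`, `n_nodes`, `n_intermediates`,
#'   `n_edges`, `compound_related_fraction` and `subnet1_fraction`
#'   (fraction of all nodes in the largest labeled sub-network; 0 when no
#'   component exceeds the labeling cutoff).
#' @export
gin_stats <- function(gin) {
  stopifnot(inherits(gin, "gin"))
  nodes <- graph_nodes(gin)
  n <- length(nodes)
  if (!n) {
    return(list(species_code = gin$species_code, n_nodes = 0L,
                n_intermediates = 0L, n_edges = 0L,
                compound_related_fraction = 0, subnet1_fraction = 0))
  }
  labeling <- label_subnets(gin)
  subnet1 <- if (length(labeling$component_sizes)) {
    unname(labeling$component_sizes[["1"]]) / n
  } else 0
  cls <- classify_nodes(gin)
  list(species_code = gin$species_code,
       n_nodes = n,
       n_intermediates = sum(startsWith(nodes, "ITM[")),
       n_edges = nrow(gin$edges),
       compound_related_fraction = mean(cls == "compound_related"),
       subnet1_fraction = subnet1)
}

#' @export
print.gin <- function(x, ...) {
  s <- gin_stats(x)
  cat("<gin> species ", x$species_code, ": ", s$n_edges, " edges, ",
      s$n_nodes, " nodes (", s$n_intermediates, " intermediates, ",
      round(100 * s$compound_related_fraction, 1), "% compound-related)\n",
      sep = "")
  invisible(x)
}
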