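# KGML reading, validation and writing.
#
# KGML is the XML dialect KEGG uses to describe one pathway: <entry> elements
# declare the molecules (genes, compounds, protein-complex groups, links to
# other maps), <reaction> elements describe metabolic conversions between
# compound entries, and <relation> elements describe signaling edges (PPrel,
# PCrel, ...). This module parses a file into a neutral in-memory
# representation; no graph semantics are attached here.

KGML_ENTRY_TYPES <- c("gene", "compound", "group", "map", "ortholog", "enzyme")

#' Parse a KGML document
#'
#' Reads KGML XML text into a `pathway_doc`: a canonically ordered, validated
#' container of entries, reactions and relations. Each reaction is linked to
#' the entries that catalyze it by matching the entries' `reaction` attribute
#' against the reaction name. Relations are classified as `PPrel`
#' (protein-protein), `PCrel` (protein-compound) or `other` (`ECrel`,
#' `maplink`, ... are retained verbatim in `rel_type_raw` but play no role in
#' graph construction).
#'
#' @param xml_text KGML content as a single string, or an `xml_document`.
#' @param check if `TRUE` (default), raise an error when a reaction or
#'   relation references an entry id that is not declared in the file;
#'   with `FALSE` the issues are left for [validate_pathway()] to report.
#' @return A `pathway_doc` object: a list with elements `pathway_id`,
#'   `species_code`, `entries`, `reactions` and `relations` (data frames
#'   with list columns for multi-valued fields).
#' @seealso [read_kgml()] to parse from a file path, [write_kgml()] for the
#'   inverse operation, [validate_pathway()] for non-fatal diagnostics.
#' @export
#' @examples
#' doc <- parse_kgml(generate_kgml(fixture_spec(seed = 1)))
#' doc
parse_kgml <- function(xml_text, check = TRUE) {
  xml <- if (inherits(xml_text, "xml_document")) {
    xml_text
  } else {
    tryCatch(
      xml2::read_xml(xml_text),
      error = function(e) {
        stop("KGML parse error: ", conditionMessage(e), call. = FALSE)
      }
    )
  }
  root <- xml2::xml_find_first(xml, "/pathway")
  if (inherits(root, "xml_missing")) {
    stop("KGML parse error: document root is not <pathway>", call. = FALSE)
  }

  pathway_name <- xml2::xml_attr(root, "name")
  pathway_id <- sub("^path:", "", ifelse(is.na(pathway_name), "", pathway_name))
  species_code <- xml2::xml_attr(root, "org")
  if (is.na(species_code)) species_code <- gsub("[0-9]", "", pathway_id)

  entry_nodes <- xml2::xml_find_all(root, "entry")
  entries <- data.frame(
    entry_id = as.integer(xml2::xml_attr(entry_nodes, "id")),
    entry_type = xml2::xml_attr(entry_nodes, "type"),
    reaction_ref = xml2::xml_attr(entry_nodes, "reaction"),
    stringsAsFactors = FALSE
  )
  entries$names <- lapply(entry_nodes, function(n) {
    nm <- xml2::xml_attr(n, "name")
    if (is.na(nm) || nm == "" || nm == "undefined") return(character(0))
    strsplit(nm, " +")[[1]]
  })
  entries$components <- lapply(entry_nodes, function(n) {
    as.integer(xml2::xml_attr(xml2::xml_find_all(n, "component"), "id"))
  })
  entries <- entries[order(entries$entry_id), , drop = FALSE]
  rownames(entries) <- NULL

  reaction_nodes <- xml2::xml_find_all(root, "reaction")
  reactions <- data.frame(
    reaction_id = xml2::xml_attr(reaction_nodes, "name"),
    direction = xml2::xml_attr(reaction_nodes, "type"),
    stringsAsFactors = FALSE
  )
  reactions$substrates <- lapply(reaction_nodes, function(n) {
    sort(as.integer(xml2::xml_attr(xml2::xml_find_all(n, "substrate"), "id")))
  })
  reactions$products <- lapply(reaction_nodes, function(n) {
    sort(as.integer(xml2::xml_attr(xml2::xml_find_all(n, "product"), "id")))
  })
  # an entry's reaction attribute may list several space-separated reaction
  # names; an entry catalyzes a reaction iff the reaction's name is among them
  ref_list <- lapply(entries$reaction_ref, function(r) {
    if (is.na(r)) character(0) else strsplit(r, " +")[[1]]
  })
  reactions$enzymes <- lapply(reactions$reaction_id, function(rid) {
    hit <- vapply(ref_list, function(refs) rid %in% refs, logical(1))
    sort(entries$entry_id[hit])
  })
  if (nrow(reactions)) {
    reactions <- reactions[order(reactions$reaction_id, reactions$direction), ,
                           drop = FALSE]
    rownames(reactions) <- NULL
  }

  relation_nodes <- xml2::xml_find_all(root, "relation")
  rel_raw <- xml2::xml_attr(relation_nodes, "type")
  relations <- data.frame(
    entry1 = as.integer(xml2::xml_attr(relation_nodes, "entry1")),
    entry2 = as.integer(xml2::xml_attr(relation_nodes, "entry2")),
    rel_type_raw = rel_raw,
    rel_type = ifelse(rel_raw %in% c("PPrel", "PCrel"), rel_raw, "other"),
    stringsAsFactors = FALSE
  )
  relations$subtypes <- lapply(relation_nodes, function(n) {
    xml2::xml_attr(xml2::xml_find_all(n, "subtype"), "name")
  })
  if (nrow(relations)) {
    key <- order(relations$entry1, relations$entry2, relations$rel_type_raw,
                 vapply(relations$subtypes, paste, character(1), collapse = ","))
    relations <- relations[key, , drop = FALSE]
    rownames(relations) <- NULL
  }

  doc <- structure(
    list(pathway_id = pathway_id, species_code = species_code,
         entries = entries, reactions = reactions, relations = relations),
    class = "pathway_doc"
  )
  if (check) {
    issues <- validate_pathway(doc)
    dangling <- issues[issues$kind == "dangling_reference", , drop = FALSE]
    if (nrow(dangling)) {
      stop("KGML validation error: dangling entry reference(s): ",
           paste(unique(dangling$element), collapse = ", "), call. = FALSE)
    }
  }
  doc
}

#' Read a KGML file
#'
#' @param path path to a `.xml` KGML file (UTF-8).
#' @param check see [parse_kgml()].
#' @return A `pathway_doc`.
#' @export
read_kgml <- function(path, check = TRUE) {
  if (!file.exists(path)) stop("KGML file not found: ", path, call. = FALSE)
  parse_kgml(xml2::read_xml(path, encoding = "UTF-8"), check = check)
}

#' Read every KGML file in a directory
#'
#' @param dir directory scanned (non-recursively) for `*.xml` files.
#' @param check see [parse_kgml()].
#' @return Named list of `pathway_doc`, named by pathway id, in sorted file
#'   order.
#' @export
read_kgml_dir <- function(dir, check = TRUE) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  if (!length(files)) stop("no kgml files found in ", dir, call. = FALSE)
  docs <- lapply(files, read_kgml, check = check)
  names(docs) <- vapply(docs, function(d) d$pathway_id, character(1))
  docs
}

#' Validate a pathway document
#'
#' Checks the structural invariants of a `pathway_doc` and returns the
#' violations as data, not errors: unknown entry types, empty name lists on
#' non-group entries, groups with fewer than two components, reactions
#' without substrates or products or with an unknown direction, and
#' reaction/relation references to undeclared entry ids.
#'
#' @param doc a `pathway_doc`.
#' @return data frame with columns `kind`, `element`, `message`; zero rows
#'   when the document is valid.
#' @export
validate_pathway <- function(doc) {
  stopifnot(inherits(doc, "pathway_doc"))
  issues <- list()
  add <- function(kind, element, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      kind = kind, element = as.character(element), message = message,
      stringsAsFactors = FALSE)
  }

  ids <- doc$entries$entry_id
  if (anyDuplicated(ids)) {
    for (d in unique(ids[duplicated(ids)])) {
      add("duplicate_entry_id", d, "entry id declared more than once")
    }
  }
  for (i in seq_len(nrow(doc$entries))) {
    e <- doc$entries[i, ]
    if (!e$entry_type %in% KGML_ENTRY_TYPES) {
      add("unknown_entry_type", e$entry_id,
          paste0("entry type '", e$entry_type, "' is not a KGML entry type"))
    }
    if (e$entry_type == "group") {
      if (length(e$components[[1]]) < 2L) {
        add("degenerate_group", e$entry_id,
            "group entry has fewer than 2 components")
      }
      if (!all(e$components[[1]] %in% ids)) {
        bad <- setdiff(e$components[[1]], ids)
        add("dangling_reference", paste(bad, collapse = ","),
            paste0("group ", e$entry_id, " references unknown entries"))
      }
    } else if (length(e$names[[1]]) == 0L) {
      add("empty_names", e$entry_id, "non-group entry has no names")
    }
  }

  for (i in seq_len(nrow(doc$reactions))) {
    r <- doc$reactions[i, ]
    if (!r$direction %in% c("reversible", "irreversible")) {
      add("bad_direction", r$reaction_id,
          paste0("direction '", r$direction, "' is not reversible/irreversible"))
    }
    if (!length(r$substrates[[1]])) {
      add("empty_substrates", r$reaction_id, "reaction has no substrates")
    }
    if (!length(r$products[[1]])) {
      add("empty_products", r$reaction_id, "reaction has no products")
    }
    refs <- c(r$substrates[[1]], r$products[[1]], r$enzymes[[1]])
    bad <- setdiff(refs, ids)
    if (length(bad)) {
      add("dangling_reference", paste(bad, collapse = ","),
          paste0("reaction ", r$reaction_id, " references unknown entries"))
    }
  }

  for (i in seq_len(nrow(doc$relations))) {
    rel <- doc$relations[i, ]
    bad <- setdiff(c(rel$entry1, rel$entry2), ids)
    if (length(bad)) {
      add("dangling_reference", paste(bad, collapse = ","),
          "relation references unknown entries")
    }
    if (!is.na(rel$entry1) && !is.na(rel$entry2) && rel$entry1 == rel$entry2) {
      add("self_relation", rel$entry1,
          "relation connects an entry to itself (preserved, flagged)")
    }
  }

  if (!length(issues)) {
    return(data.frame(kind = character(0), element = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

#' Serialize a pathway document back to KGML
#'
#' Inverse of [parse_kgml()]: `parse_kgml(write_kgml(doc))` reproduces `doc`
#' field by field. Graphics attributes, which the parser drops, are not
#' emitted.
#'
#' @param doc a `pathway_doc`.
#' @param path optional file path; when given, the XML is written there
#'   (UTF-8) and the path returned invisibly. Otherwise the XML is returned
#'   as a character string.
#' @export
write_kgml <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "pathway_doc"))
  root <- xml2::xml_new_root(
    "pathway",
    name = paste0("path:", doc$pathway_id),
    org = doc$species_code,
    title = doc$pathway_id
  )
  first_name <- function(entry_id) {
    nm <- doc$entries$names[[match(entry_id, doc$entries$entry_id)]]
    if (length(nm)) nm[[1]] else "undefined"
  }
  for (i in seq_len(nrow(doc$entries))) {
    e <- doc$entries[i, ]
    nm <- if (length(e$names[[1]])) paste(e$names[[1]], collapse = " ") else "undefined"
    node <- xml2::xml_add_child(root, "entry", id = as.character(e$entry_id),
                                name = nm, type = e$entry_type)
    if (!is.na(e$reaction_ref)) xml2::xml_set_attr(node, "reaction", e$reaction_ref)
    for (cid in e$components[[1]]) {
      xml2::xml_add_child(node, "component", id = as.character(cid))
    }
  }
  for (i in seq_len(nrow(doc$relations))) {
    rel <- doc$relations[i, ]
    node <- xml2::xml_add_child(root, "relation",
                                entry1 = as.character(rel$entry1),
                                entry2 = as.character(rel$entry2),
                                type = rel$rel_type_raw)
    for (st in rel$subtypes[[1]]) {
      xml2::xml_add_child(node, "subtype", name = st, value = "-")
    }
  }
  for (i in seq_len(nrow(doc$reactions))) {
    r <- doc$reactions[i, ]
    node <- xml2::xml_add_child(root, "reaction", id = as.character(i),
                                name = r$reaction_id, type = r$direction)
    for (sid in r$substrates[[1]]) {
      xml2::xml_add_child(node, "substrate", id = as.character(sid),
                          name = first_name(sid))
    }
    for (pid in r$products[[1]]) {
      xml2::xml_add_child(node, "product", id = as.character(pid),
                          name = first_name(pid))
    }
  }
  if (is.null(path)) {
    as.character(root)
  } else {
    xml2::write_xml(root, path)
    invisible(path)
  }
}

#' @export
print.pathway_doc <- function(x, ...) {
  cat("<pathway_doc> ", x$pathway_id, " (species: ", x$species_code, ")\n",
      sep = "")
  cat("  entries:   ", nrow(x$entries), " (",
      paste(names(table(x$entries$entry_type)),
            table(x$entries$entry_type), sep = ":", collapse = ", "),
      ")\n", sep = "")
  cat("  reactions: ", nrow(x$reactions), "\n", sep = "")
  cat("  relations: ", nrow(x$relations), " (",
      sum(x$relations$rel_type != "other"), " PPrel/PCrel)\n", sep = "")
  invisible(x)
}
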