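# Protein-complex expansion.
#
# KGML "group" entries describe protein complexes whose slots may hold
# alternative subunits: a complex A+(B/C)+D is stored as a group of three
# member entries where the middle entry lists B and C as alternatives
# (KEGG also uses multi-name entries for isoenzymes). Such a group is
# expanded into one concrete enzyme unit per element of the Cartesian
# product of the alternative sets — here ABD and ACD. Homo-oligomers
# collapse: repeated members within one unit are stored once, so a
# homodimer A+A is the single unit A.

#' Canonical identifier of an enzyme unit
#'
#' A unit with one member is identified by that member's id; a multi-member
#' complex gets the id `CPLX[m1+m2+...]` over its lexicographically sorted,
#' de-duplicated members. KEGG identifiers contain no `+`, `[` or `]`, so the
#' scheme is collision-free and invertible (see [unit_members()]).
#'
#' @param members character vector of gene identifiers, length >= 1.
#' @return single string.
#' @export
enzyme_unit_id <- function(members) {
  members <- sort(unique(as.character(members)))
  if (!length(members)) stop("enzyme unit needs at least one member", call. = FALSE)
  if (length(members) == 1L) members else {
    paste0("CPLX[", paste(members, collapse = "+"), "]")
  }
}

#' Members of an enzyme unit
#'
#' @param unit_id a unit id produced by [enzyme_unit_id()].
#' @return sorted character vector of member identifiers.
#' @export
unit_members <- function(unit_id) {
  if (startsWith(unit_id, "CPLX[")) {
    strsplit(substr(unit_id, 6L, nchar(unit_id) - 1L), "+", fixed = TRUE)[[1]]
  } else {
    unit_id
  }
}

#' Expand a group of alternative subunits into concrete enzyme units
#'
#' Takes one identifier set per complex slot and enumerates the Cartesian
#' product of the alternatives. Duplicate members within a unit are collapsed
#' (homodimers become monomer units) and duplicate units arising from
#' different choices are removed.
#'
#' @param member_alternatives list of non-empty character vectors, one per
#'   slot; order of slots and of alternatives within a slot is irrelevant.
#' @param group_id optional label used in error messages.
#' @return sorted character vector of unit ids (see [enzyme_unit_id()]).
#' @export
#' @examples
#' expand_group(list("A", c("B", "C"), "D"))  # CPLX[A+B+D], CPLX[A+C+D]
#' expand_group(list("A", "A"))               # homodimer -> "A"
expand_group <- function(member_alternatives, group_id = "group") {
  stopifnot(is.list(member_alternatives), length(member_alternatives) >= 1L)
  sizes <- lengths(member_alternatives)
  if (any(sizes == 0L)) {
    stop("empty alternative set in ", group_id, call. = FALSE)
  }
  combos <- expand.grid(member_alternatives, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  units <- apply(combos, 1L, function(row) enzyme_unit_id(unlist(row)))
  sort(unique(unname(units)))
}

#' Subunit-to-complex edges of an enzyme unit
#'
#' A multi-member complex contributes one type-1 edge per member, directed
#' member -> complex, with neutral sign. A monomer is not a complex and
#' contributes nothing.
#'
#' @param unit_id enzyme unit id.
#' @param pathway_id provenance string recorded on the edges.
#' @return a meta-edge data frame (possibly zero rows); see [meta_edges()].
#' @export
complex_edges <- function(unit_id, pathway_id = "") {
  members <- unit_members(unit_id)
  if (length(members) < 2L) return(empty_meta_edges())
  meta_edges(source = members, target = unit_id, edge_type = 1L,
             sign = "neutral", pathway_id = pathway_id)
}

#' Resolve a KGML entry to its enzyme units
#'
#' Gene/enzyme/ortholog entries listing several identifiers are isoenzyme
#' alternatives: each name becomes its own single-member unit. Group entries
#' are expanded with [expand_group()]; each component contributes its name
#' set as one alternative slot, and nested groups are flattened recursively.
#' Compound entries yield their compound ids unchanged.
#'
#' @param doc a `pathway_doc`.
#' @param entry_id file-local entry id.
#' @return character vector of unit ids (or compound ids), sorted.
#' @export
entry_units <- function(doc, entry_id) {
  i <- match(entry_id, doc$entries$entry_id)
  if (is.na(i)) {
    stop("unknown entry id ", entry_id, " in pathway ", doc$pathway_id,
         call. = FALSE)
  }
  type <- doc$entries$entry_type[[i]]
  if (type != "group") {
    return(sort(unique(doc$entries$names[[i]])))
  }
  slots <- lapply(doc$entries$components[[i]], function(cid) {
    entry_units(doc, cid)  # flattens nested groups: their units become alternatives
  })
  expand_group(lapply(slots, function(s) {
    # a nested complex unit participating as a slot keeps its members:
    # flatten so that the final unit lists gene ids, not CPLX ids
    unique(unlist(lapply(s, unit_members)))
  }), group_id = paste0("group entry ", entry_id))
}

#' Export the complex reference table of a set of pathways
#'
#' Collects every complex unit reachable from the group entries of the given
#' documents and writes a two-column TSV: unit id, comma-joined members.
#'
#' @param docs list of `pathway_doc`.
#' @param path output TSV path; when `NULL`, the table is returned only.
#' @return data frame with columns `unit_id` and `members`, invisibly when
#'   written to file.
#' @export
complex_reference <- function(docs, path = NULL) {
  if (inherits(docs, "pathway_doc")) docs <- list(docs)
  units <- character(0)
  for (doc in docs) {
    groups <- doc$entries$entry_id[doc$entries$entry_type == "group"]
    for (g in groups) units <- c(units, entry_units(doc, g))
  }
  units <- sort(unique(units[startsWith(units, "CPLX[")]))
  out <- data.frame(
    unit_id = units,
    members = vapply(units, function(u) paste(unit_members(u), collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(out))
  }
  out
}
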