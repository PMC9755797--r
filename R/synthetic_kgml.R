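# Seeded synthetic KGML generator.
#
# Emulates the structural repertoire of real KEGG pathway files — gene,
# compound, group and map entries, reversible and irreversible reactions,
# multi-isoenzyme reactions, groups with alternative subunits, PPrel/PCrel
# relations with activation/inhibition subtypes — so that every pipeline
# stage can be exercised offline. Identifiers live in reserved namespaces
# ("syn:NNNN" genes, "cpd:C9NNNN" compounds) that exercise node-class
# detection without colliding with real KEGG ids. The generator targets
# structural coverage, not statistical realism (no attempt at KEGG-like
# degree distributions).

# --- incremental pathway_doc builder -------------------------------------

doc_builder <- function(pathway_id, species_code) {
  env <- new.env(parent = emptyenv())
  env$pathway_id <- pathway_id
  env$species_code <- species_code
  env$entries <- list()
  env$reactions <- list()
  env$relations <- list()
  env
}

add_entry <- function(b, entry_type, names, reaction_ref = NA_character_,
                      components = integer(0)) {
  id <- length(b$entries) + 1L
  b$entries[[id]] <- list(entry_id = id, entry_type = entry_type,
                          names = as.character(names),
                          reaction_ref = reaction_ref,
                          components = as.integer(components))
  id
}

add_reaction <- function(b, reaction_id, substrates, products,
                         direction = "irreversible") {
  b$reactions[[length(b$reactions) + 1L]] <-
    list(reaction_id = reaction_id, direction = direction,
         substrates = as.integer(substrates), products = as.integer(products))
  invisible(NULL)
}

add_relation <- function(b, entry1, entry2, rel_type, subtypes = character(0)) {
  b$relations[[length(b$relations) + 1L]] <-
    list(entry1 = as.integer(entry1), entry2 = as.integer(entry2),
         rel_type = rel_type, subtypes = as.character(subtypes))
  invisible(NULL)
}

build_doc <- function(b) {
  entries <- data.frame(
    entry_id = vapply(b$entries, `[[`, integer(1), "entry_id"),
    entry_type = vapply(b$entries, `[[`, character(1), "entry_type"),
    reaction_ref = vapply(b$entries, `[[`, character(1), "reaction_ref"),
    stringsAsFactors = FALSE
  )
  entries$names <- lapply(b$entries, `[[`, "names")
  entries$components <- lapply(b$entries, `[[`, "components")
  reactions <- data.frame(
    reaction_id = vapply(b$reactions, `[[`, character(1), "reaction_id"),
    direction = vapply(b$reactions, `[[`, character(1), "direction"),
    stringsAsFactors = FALSE
  )
  reactions$substrates <- lapply(b$reactions, function(r) sort(r$substrates))
  reactions$products <- lapply(b$reactions, function(r) sort(r$products))
  ref_list <- lapply(entries$reaction_ref,
                     function(r) if (is.na(r)) character(0) else
                       strsplit(r, " +")[[1]])
  reactions$enzymes <- lapply(reactions$reaction_id, function(rid) {
    hit <- vapply(ref_list, function(refs) rid %in% refs, logical(1))
    sort(entries$entry_id[hit])
  })
  relations <- data.frame(
    entry1 = vapply(b$relations, `[[`, integer(1), "entry1"),
    entry2 = vapply(b$relations, `[[`, integer(1), "entry2"),
    rel_type_raw = vapply(b$relations, `[[`, character(1), "rel_type"),
    stringsAsFactors = FALSE
  )
  relations$rel_type <- ifelse(relations$rel_type_raw %in% c("PPrel", "PCrel"),
                               relations$rel_type_raw, "other")
  relations$subtypes <- lapply(b$relations, `[[`, "subtypes")
  doc <- structure(
    list(pathway_id = b$pathway_id, species_code = b$species_code,
         entries = entries, reactions = reactions, relations = relations),
    class = "pathway_doc"
  )
  # canonicalize ordering (and re-check invariants) through the parser
  parse_kgml(write_kgml(doc))
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# --- fixture spec ---------------------------------------------------------

#' Specification of a synthetic KGML fixture
#'
#' @param seed integer RNG seed; the same spec always yields byte-identical
#'   output.
#' @param n_genes,n_compounds,n_reactions,n_relations counts of random
#'   background elements.
#' @param p_reversible probability that a random reaction is reversible.
#' @param p_group probability that a random reaction is catalyzed by a
#'   protein complex group (with one two-alternative subunit slot).
#' @param p_isoenzyme probability that a random enzyme entry lists two
#'   isoenzyme gene ids.
#' @param motifs character vector of planted structural templates:
#'   `"fig1c"` (a three-gene signaling cascade whose terminal kinase
#'   catalyzes a compound conversion, so the cascade and the reaction join
#'   through the enzyme->intermediate edge) and `"oxtr_artifact"` (a
#'   compound spuriously activating a receptor, the shape that curation is
#'   meant to remove).
#' @param pathway_id,species_code identifiers of the emitted pathway.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 10L, n_compounds = 8L,
                         n_reactions = 5L, n_relations = 6L,
                         p_reversible = 0.3, p_group = 0.25,
                         p_isoenzyme = 0.25, motifs = "fig1c",
                         pathway_id = "syn00001", species_code = "syn") {
  stopifnot(n_genes >= 0L, n_compounds >= 0L, n_reactions >= 0L,
            n_relations >= 0L,
            p_reversible >= 0, p_reversible <= 1,
            p_group >= 0, p_group <= 1,
            p_isoenzyme >= 0, p_isoenzyme <= 1)
  if (n_reactions > 0L && n_compounds < 2L) {
    stop("cannot generate reactions with fewer than 2 compounds",
         call. = FALSE)
  }
  if (n_relations > 0L && n_genes < 2L) {
    stop("cannot generate relations with fewer than 2 genes", call. = FALSE)
  }
  bad <- setdiff(motifs, c("fig1c", "oxtr_artifact"))
  if (length(bad)) stop("unknown motif(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_compounds = as.integer(n_compounds),
                 n_reactions = as.integer(n_reactions),
                 n_relations = as.integer(n_relations),
                 p_reversible = p_reversible, p_group = p_group,
                 p_isoenzyme = p_isoenzyme, motifs = motifs,
                 pathway_id = pathway_id, species_code = species_code),
            class = "fixture_spec")
}

# reserved ids used by the planted motifs (outside the random ranges)
FIG1C_NODES <- c(A = "syn:8001", B = "syn:8002", C = "syn:8003",
                 F = "cpd:C98001", G = "cpd:C98002")
OXTR_NODES <- c(ligand = "cpd:C98101", receptor = "syn:8101")

#' Generate one synthetic KGML file
#'
#' Deterministically emits a KGML document that parses under
#' [parse_kgml()] with zero validation issues and contains the planted
#' motifs of the spec verbatim.
#'
#' @param spec a [fixture_spec()].
#' @param path optional output file; when `NULL` the XML is returned as a
#'   string.
#' @return XML string, or `path` invisibly.
#' @export
generate_kgml <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  doc <- with_local_seed(spec$seed, {
    b <- doc_builder(spec$pathway_id, spec$species_code)
    gene_ids <- vapply(seq_len(spec$n_genes), function(i) {
      add_entry(b, "gene", sprintf("syn:%04d", i))
    }, integer(1))
    cpd_ids <- vapply(seq_len(spec$n_compounds), function(i) {
      add_entry(b, "compound", sprintf("cpd:C90%03d", i))
    }, integer(1))

    for (k in seq_len(spec$n_reactions)) {
      rid <- sprintf("rn:R9%04d", k)
      sub_n <- if (stats::runif(1) < 0.25) 2L else 1L
      subs <- sample(cpd_ids, min(sub_n, length(cpd_ids) - 1L))
      prods <- sample(setdiff(cpd_ids, subs), 1L)
      dir <- if (stats::runif(1) < spec$p_reversible) "reversible" else
        "irreversible"
      if (length(gene_ids) && stats::runif(1) < spec$p_group) {
        # complex enzyme: fixed subunit + one slot with two alternatives
        s1 <- add_entry(b, "gene", sprintf("syn:7%03d", 2L * k - 1L))
        s2 <- add_entry(b, "gene",
                        sprintf("syn:7%03d", c(2L * k, 2L * k + 500L)))
        add_entry(b, "group", character(0), reaction_ref = rid,
                  components = c(s1, s2))
      } else if (length(gene_ids)) {
        n_names <- if (stats::runif(1) < spec$p_isoenzyme) 2L else 1L
        add_entry(b, "gene",
                  sprintf("syn:6%03d", (2L * k - 1L):(2L * k - 2L + n_names)),
                  reaction_ref = rid)
      }
      add_reaction(b, rid, subs, prods, dir)
    }

    subtype_pool <- c("activation", "inhibition", "binding/association",
                      "phosphorylation")
    for (k in seq_len(spec$n_relations)) {
      if (length(cpd_ids) && stats::runif(1) < 0.25) {
        add_relation(b, sample(cpd_ids, 1L), sample(gene_ids, 1L), "PCrel",
                     sample(subtype_pool, 1L))
      } else {
        pair <- sample(gene_ids, 2L)
        add_relation(b, pair[[1]], pair[[2]], "PPrel",
                     sample(subtype_pool, 1L))
      }
    }

    if ("fig1c" %in% spec$motifs) {
      a <- add_entry(b, "gene", FIG1C_NODES[["A"]])
      bb <- add_entry(b, "gene", FIG1C_NODES[["B"]])
      cc <- add_entry(b, "gene", FIG1C_NODES[["C"]], reaction_ref = "rn:R98001")
      f <- add_entry(b, "compound", FIG1C_NODES[["F"]])
      g <- add_entry(b, "compound", FIG1C_NODES[["G"]])
      add_relation(b, a, bb, "PPrel", "activation")
      add_relation(b, bb, cc, "PPrel", "activation")
      add_reaction(b, "rn:R98001", f, g, "irreversible")
    }
    if ("oxtr_artifact" %in% spec$motifs) {
      lig <- add_entry(b, "compound", OXTR_NODES[["ligand"]])
      rec <- add_entry(b, "gene", OXTR_NODES[["receptor"]])
      add_relation(b, lig, rec, "PCrel", "activation")
    }
    build_doc(b)
  })
  xml <- write_kgml(doc)
  if (is.null(path)) return(xml)
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}

#' Generate a crosstalk fixture: two pathways with planted bridges
#'
#' Emits a metabolic-style pathway and a signaling-style pathway whose
#' exclusive member sets are disjoint, connected in the merged GIN through
#' planted linker molecules (which belong to both files and are therefore
#' excluded from the crosstalk endpoint sets):
#'
#' * outgoing bridge (A to B): a compound of A is converted (uncatalyzed)
#'   into a linker compound that activates a receptor in B — retained path
#'   of 5 nodes, weight `(2/5)^2`;
#' * a longer alternative out-route via a second linker and a relay
#'   protein (7 nodes to the same receptor), which must lose to the
#'   5-node path;
#' * incoming bridge (B to A): a kinase of B inhibits a linker enzyme
#'   that catalyzes a reaction of A — retained path of 5 nodes;
#' * an artifact edge in the style of a misassigned ligand-receptor
#'   activation: linker compound -> artifact receptor. The accompanying
#'   curation rule disconnects that receptor entirely.
#'
#' @param seed integer; seeds the decoy background of each file.
#' @param dir optional directory: when given, the two KGML files and a
#'   YAML manifest are written there.
#' @return list with `doc_a`, `doc_b` (`pathway_doc`), `curation` (data
#'   frame) and `manifest` (expected members, retained paths, distances,
#'   weights and the artifact pair).
#' @export
generate_crosstalk_pair <- function(seed = 1L, dir = NULL) {
  # pathway A: metabolic side
  ba <- doc_builder("syn09001", "syn")
  ka0 <- add_entry(ba, "compound", "cpd:C91000")
  ka1 <- add_entry(ba, "compound", "cpd:C91001")
  ka2 <- add_entry(ba, "compound", "cpd:C91002")
  ka3 <- add_entry(ba, "compound", "cpd:C91003")
  l1 <- add_entry(ba, "compound", "cpd:C91900")  # linker, also in B
  l2 <- add_entry(ba, "compound", "cpd:C91901")  # linker, also in B
  ga1 <- add_entry(ba, "gene", "syn:9101", reaction_ref = "rn:R91001")
  m <- add_entry(ba, "gene", "syn:9900", reaction_ref = "rn:R91002")  # linker enzyme
  add_reaction(ba, "rn:R91001", ka0, ka1)
  add_reaction(ba, "rn:R91002", ka2, ka3)
  add_reaction(ba, "rn:R91003", ka1, l1)   # out-bridge, uncatalyzed
  add_reaction(ba, "rn:R91004", ka1, l2)   # longer alternative out-route

  # pathway B: signaling side
  bb <- doc_builder("syn09002", "syn")
  k0 <- add_entry(bb, "gene", "syn:9301")
  k1 <- add_entry(bb, "gene", "syn:9302")
  r1 <- add_entry(bb, "gene", "syn:9401")
  r2 <- add_entry(bb, "gene", "syn:9402")
  relay <- add_entry(bb, "gene", "syn:9201")
  gox <- add_entry(bb, "gene", "syn:9501")  # artifact receptor
  mb <- add_entry(bb, "gene", "syn:9900")   # linker enzyme, also in A
  lb1 <- add_entry(bb, "compound", "cpd:C91900")
  lb2 <- add_entry(bb, "compound", "cpd:C91901")
  add_relation(bb, k0, k1, "PPrel", "activation")
  add_relation(bb, lb1, r1, "PCrel", "activation")
  add_relation(bb, r1, r2, "PPrel", "activation")
  add_relation(bb, lb2, relay, "PCrel", "activation")
  add_relation(bb, relay, r1, "PPrel", "activation")
  add_relation(bb, lb1, gox, "PCrel", "activation")  # planted artifact
  add_relation(bb, k1, mb, "PPrel", "inhibition")    # in-bridge

  # seeded decoys: isolated background genes, no connectivity impact
  with_local_seed(seed, {
    for (i in sample(100:999, 3L)) {
      add_entry(ba, "gene", sprintf("syn:5%03d", i))
      add_entry(bb, "gene", sprintf("syn:4%03d", i))
    }
  })

  doc_a <- build_doc(ba)
  doc_b <- build_doc(bb)

  itm <- intermediate_id
  out_path <- c("cpd:C91001", itm("cpd:C91001"), "cpd:C91900",
                itm("syn:9401", "cpd:C91900"), "syn:9401")
  in_path <- c("syn:9302", itm("syn:9900", "syn:9302"), "syn:9900",
               itm("cpd:C91002", "syn:9900"), "cpd:C91003")
  curation <- data.frame(source = "cpd:C91900", target = "syn:9501",
                         reason = "misassigned ligand-receptor activation",
                         stringsAsFactors = FALSE)
  manifest <- list(
    pathway_a = doc_a$pathway_id,
    pathway_b = doc_b$pathway_id,
    shared_members = c("cpd:C91900", "cpd:C91901", "syn:9900"),
    retained = list(
      a_to_b = list(path = out_path, distance = 5, weight = (2 / 5)^2),
      b_to_a = list(path = in_path, distance = 5, weight = (2 / 5)^2)
    ),
    artifact = list(source = "cpd:C91900", target = "syn:9501",
                    affected_pair = c("cpd:C91001", "syn:9501"),
                    distance_before = 5)
  )
  out <- list(doc_a = doc_a, doc_b = doc_b, curation = curation,
              manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_kgml(doc_a, file.path(dir, paste0(doc_a$pathway_id, ".xml")))
    write_kgml(doc_b, file.path(dir, paste0(doc_b$pathway_id, ".xml")))
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
    yaml::write_yaml(lapply(seq_len(nrow(curation)), function(i)
      as.list(curation[i, ])), file.path(dir, "curation.yaml"))
  }
  out
}

#' Generate a directory of synthetic KGML fixtures
#'
#' Convenience wrapper writing `n_pathways` files derived from one base
#' spec, with per-file seeds `seed, seed+1, ...` and pathway ids
#' `syn00001, syn00002, ...`. Motifs are planted only in the first file.
#'
#' @param spec base [fixture_spec()].
#' @param n_pathways number of files.
#' @param dir output directory (created).
#' @return character vector of file paths.
#' @export
generate_kgml_dir <- function(spec, n_pathways, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vapply(seq_len(n_pathways), function(i) {
    s <- spec
    s$seed <- spec$seed + i - 1L
    s$pathway_id <- sprintf("syn%05d", i)
    if (i > 1L) s$motifs <- character(0)
    generate_kgml(s, file.path(dir, paste0(s$pathway_id, ".xml")))
    file.path(dir, paste0(s$pathway_id, ".xml"))
  }, character(1))
}
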