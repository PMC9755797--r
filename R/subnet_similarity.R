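# Cross-species sub-network comparison.
#
# Sub-networks of different species cannot be compared by gene identifiers
# directly, so genes are first mapped to KEGG Orthology (KO) ids; compounds
# already share a species-independent namespace. Each labeled sub-network
# is then reduced to a feature set of KO ids plus compound ids —
# intermediates and complexes are derived constructs and excluded — and
# pairs of sub-networks are scored with the Jaccard index
# |A intersect B| / |A union B|.

#' Read a gene-to-KO mapping table
#'
#' @param path two-column TSV (gene id, KO id), no header. A gene may map
#'   to several KOs on separate lines.
#' @return data frame with columns `gene` and `ko`.
#' @export
read_ko_mapping <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene", "ko"),
                           colClasses = "character", quote = "",
                           comment.char = "#")
  tab
}

#' Map gene ids to KO ids
#'
#' @param genes character vector/set of gene ids.
#' @param mapping data frame with columns `gene` and `ko` (see
#'   [read_ko_mapping()]).
#' @return list with `ko` (sorted set of KO ids) and `unmapped` (sorted
#'   genes absent from the mapping; reported, never fatal).
#' @export
map_to_ko <- function(genes, mapping) {
  genes <- unique(as.character(genes))
  hit <- mapping$gene %in% genes
  list(ko = sort(unique(mapping$ko[hit])),
       unmapped = sort(setdiff(genes, mapping$gene)))
}

#' Feature sets of labeled sub-networks
#'
#' For every labeled sub-network, collects its gene nodes (mapped to KO
#' ids) and compound nodes into one feature set. Intermediate and complex
#' nodes are skipped; genes without a KO mapping are dropped and counted.
#'
#' @param gin a `gin`.
#' @param labeling a `subnet_labeling` from [label_subnets()]; computed
#'   from `gin` when omitted.
#' @param ko_mapping gene-to-KO data frame; `NULL` keeps raw gene ids
#'   (same-species comparisons).
#' @return list of `feature_set` objects keyed by subnet label, each a
#'   list with `subnet_label`, `features` (sorted character set) and
#'   `n_unmapped`.
#' @export
subnet_features <- function(gin, labeling = NULL, ko_mapping = NULL) {
  if (is.null(labeling)) labeling <- label_subnets(gin)
  labels <- sort(unique(labeling$assignments))
  out <- lapply(labels, function(lab) {
    nodes <- names(labeling$assignments)[labeling$assignments == lab]
    cls <- node_class(nodes)
    compounds <- nodes[cls == "compound"]
    genes <- nodes[cls == "gene"]
    n_unmapped <- 0L
    if (!is.null(ko_mapping)) {
      m <- map_to_ko(genes, ko_mapping)
      genes <- m$ko
      n_unmapped <- length(m$unmapped)
    }
    structure(list(subnet_label = lab,
                   features = sort(unique(c(genes, compounds))),
                   n_unmapped = n_unmapped),
              class = "feature_set")
  })
  names(out) <- as.character(labels)
  out
}

#' Jaccard score of two feature sets
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both sets are empty.
#'
#' @param a,b `feature_set` objects or plain character vectors.
#' @return numeric in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  fa <- if (inherits(a, "feature_set")) a$features else unique(as.character(a))
  fb <- if (inherits(b, "feature_set")) b$features else unique(as.character(b))
  u <- length(union(fa, fb))
  if (u == 0L) return(0)
  length(intersect(fa, fb)) / u
}

#' Pairwise Jaccard matrix between two species' sub-networks
#'
#' @param subnets_a,subnets_b named lists of `feature_set` (see
#'   [subnet_features()]), e.g. for two species mapped to the common KO
#'   namespace.
#' @param exclude_subnet1 drop the label-1 sub-network (the dominant
#'   assembled component) from both sides so that only the detached pieces
#'   are compared.
#' @return numeric matrix, rows = subnets of A, cols = subnets of B,
#'   dimnames = subnet labels.
#' @export
jaccard_matrix <- function(subnets_a, subnets_b, exclude_subnet1 = FALSE) {
  drop1 <- function(s) s[vapply(s, function(f) f$subnet_label != 1L, logical(1))]
  if (exclude_subnet1) {
    subnets_a <- drop1(subnets_a)
    subnets_b <- drop1(subnets_b)
  }
  m <- matrix(0, nrow = length(subnets_a), ncol = length(subnets_b),
              dimnames = list(names(subnets_a), names(subnets_b)))
  for (i in seq_along(subnets_a)) {
    for (j in seq_along(subnets_b)) {
      m[i, j] <- jaccard(subnets_a[[i]], subnets_b[[j]])
    }
  }
  m
}

#' Matched sub-network pairs
#'
#' Operationalizes "subnet X of species A matches subnet Y of species B"
#' as a Jaccard score at or above a threshold.
#'
#' @param scores matrix from [jaccard_matrix()].
#' @param threshold minimum score counted as a match (default 0.5).
#' @return data frame with columns `subnet_a`, `subnet_b`, `score`,
#'   ordered by decreasing score.
#' @export
matched_subnets <- function(scores, threshold = 0.5) {
  hit <- which(scores >= threshold, arr.ind = TRUE)
  out <- data.frame(
    subnet_a = rownames(scores)[hit[, 1L]],
    subnet_b = colnames(scores)[hit[, 2L]],
    score = scores[hit],
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score, out$subnet_a, out$subnet_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
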