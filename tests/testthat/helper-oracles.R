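# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph) so they can arbitrate correctness.

# recursive Cartesian enumeration of alternative subunit sets; returns the
# de-duplicated list of sorted member vectors
oracle_expand_group <- function(alternatives) {
  combos <- list(character(0))
  for (slot in alternatives) {
    combos <- unlist(lapply(combos, function(cur) {
      lapply(slot, function(x) c(cur, x))
    }), recursive = FALSE)
  }
  units <- lapply(combos, function(m) sort(unique(m)))
  unique(units[order(vapply(units, paste, character(1), collapse = "+"))])
}

# union-find weak components; returns named integer membership vector
oracle_components <- function(nodes, edges) {
  parent <- seq_along(nodes)
  idx <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  for (k in seq_len(nrow(edges))) {
    ri <- find(idx[[edges$source[[k]]]])
    rj <- find(idx[[edges$target[[k]]]])
    if (ri != rj) parent[[rj]] <- ri
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  stats::setNames(match(roots, unique(roots)), nodes)
}

# Floyd-Warshall all-pairs shortest-path edge counts (Inf = unreachable)
oracle_floyd_warshall <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  d[cbind(edges$source, edges$target)] <- 1
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# plain double-loop Jaccard over raw character sets
oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(unique(c(a, b)))
  if (u == 0) 0 else sum(a %in% b) / u
}
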