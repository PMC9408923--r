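# Canonical labelling of small loopless multigraphs.
#
# Exact canonicalisation for the vertex counts handled here (V <= 9): iterated
# degree/neighbourhood refinement partitions the vertices into invariantly
# ordered colour classes, then a search over class-preserving permutations
# picks the lexicographically smallest upper-triangle multiplicity vector.

#' Invariant colour refinement of a weighted adjacency matrix
#'
#' Colours start from (degree, sorted incident multiplicities) and are refined
#' by the sorted multiset of (edge multiplicity, neighbour colour) until
#' stable. Class numbering is by signature string, so it is identical for
#' isomorphic graphs.
#' @param adj symmetric integer matrix (zero diagonal)
#' @return integer vector of colours 1..k
#' @noRd
wl_colors <- function(adj) {
  V <- nrow(adj)
  if (V == 1L) return(1L)
  sig <- vapply(seq_len(V), function(v) {
    paste0("d", sum(adj[v, ]), "m", paste(sort(adj[v, adj[v, ] > 0L]), collapse = "."))
  }, character(1L))
  colors <- match(sig, sort(unique(sig)))
  repeat {
    sig <- vapply(seq_len(V), function(v) {
      nb <- which(adj[v, ] > 0L)
      paste0(colors[v], "|",
             paste(sort(paste0(adj[v, nb], ":", colors[nb])), collapse = ","))
    }, character(1L))
    new_colors <- match(sig, sort(unique(sig)))
    if (identical(new_colors, colors)) break
    colors <- new_colors
  }
  colors
}

#' All permutations of 1..n (n small)
#' @noRd
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

#' Permutations of vertices that respect colour classes
#'
#' Returns permutations p (new position -> original vertex) such that vertices
#' are listed class by class, permuted arbitrarily within each class.
#' @noRd
class_perms <- function(colors) {
  classes <- split(seq_along(colors), colors)
  per_class <- lapply(classes, function(cl) {
    lapply(all_perms(length(cl)), function(p) cl[p])
  })
  out <- list(integer(0))
  for (pc in per_class) {
    out <- unlist(lapply(out, function(prefix) {
      lapply(pc, function(tail) c(prefix, tail))
    }), recursive = FALSE)
  }
  out
}

adj_key <- function(adj) {
  if (nrow(adj) < 2L) return("")
  paste(adj[upper.tri(adj)], collapse = ",")
}

#' Canonical certificate of a loopless multigraph
#'
#' Two graphs have equal certificates exactly when they are isomorphic as
#' multigraphs (self-loops must be stripped by the caller). The certificate is
#' `"V:"` followed by the lexicographically smallest upper-triangle
#' multiplicity vector over all colour-class-preserving relabellings.
#'
#' @param adj symmetric integer multiplicity matrix with zero diagonal, or a
#'   `dual_graph`
#' @return certificate string
#' @export
canonical_certificate <- function(adj) {
  if (inherits(adj, "dual_graph")) adj <- adj$edge_mult
  V <- nrow(adj)
  if (V == 0L) return("0:")
  if (V == 1L) return("1:")
  colors <- wl_colors(adj)
  best <- NULL
  for (p in class_perms(colors)) {
    key <- adj[p, p][upper.tri(adj)]
    keystr <- paste(key, collapse = ",")
    if (is.null(best) || keystr < best) best <- keystr
  }
  paste0(V, ":", best)
}

#' Canonically relabelled adjacency matrix (certificate representative)
#' @noRd
canonical_adj <- function(adj) {
  V <- nrow(adj)
  if (V <= 1L) return(adj)
  colors <- wl_colors(adj)
  best <- NULL; best_p <- NULL
  for (p in class_perms(colors)) {
    keystr <- paste(adj[p, p][upper.tri(adj)], collapse = ",")
    if (is.null(best) || keystr < best) { best <- keystr; best_p <- p }
  }
  adj[best_p, best_p]
}

#' Automorphisms of a loopless multigraph
#' @param adj symmetric integer matrix
#' @return list of permutation vectors p with adj[p,p] == adj
#' @noRd
automorphism_perms <- function(adj) {
  V <- nrow(adj)
  if (V <= 1L) return(list(seq_len(V)))
  colors <- wl_colors(adj)
  Filter(function(p) all(adj[p, p] == adj), class_perms(colors))
}

#' Brute-force multigraph isomorphism test (test oracle)
#'
#' Checks all V! permutations; intended for small V in cross-checks.
#' @param a,b symmetric integer multiplicity matrices
#' @return logical
#' @export
isomorphic_bruteforce <- function(a, b) {
  if (nrow(a) != nrow(b)) return(FALSE)
  if (nrow(a) <= 1L) return(TRUE)
  for (p in all_perms(nrow(a))) {
    if (all(a[p, p] == b)) return(TRUE)
  }
  FALSE
}
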