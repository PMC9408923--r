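# Shared helpers: small multigraph construction and independent oracles.

# adjacency matrix from an edge list of c(u, v, multiplicity)
mk_adj <- function(V, edges) {
  a <- matrix(0L, V, V)
  for (e in edges) {
    a[e[1L], e[2L]] <- a[e[1L], e[2L]] + e[3L]
    a[e[2L], e[1L]] <- a[e[2L], e[1L]] + e[3L]
  }
  a
}

# worked-example graphs used across test files
adj_4_16_structure <- function() {
  # unit triangle with a pendant vertex attached by a double edge
  mk_adj(4L, list(c(1, 2, 1), c(2, 3, 1), c(3, 1, 1), c(2, 4, 2)))
}

adj_5_79_structure <- function() {
  # triple-edge block -- bridge -- triangle{1,2,2} (attached at a degree-3 vertex)
  mk_adj(5L, list(c(1, 2, 3), c(2, 3, 1), c(3, 4, 2), c(3, 5, 1), c(4, 5, 2)))
}

clover_dotbracket <- function() "((((..((..))..((..))..((..))..))))"

# independent articulation-point oracle: vertex deletion + connectivity check
articulation_oracle <- function(adj) {
  V <- nrow(adj)
  if (V <= 2L) return(integer(0))
  connected <- function(a) {
    n <- nrow(a)
    seen <- logical(n); seen[1L] <- TRUE; frontier <- 1L
    while (length(frontier)) {
      nxt <- which(colSums(a[frontier, , drop = FALSE] > 0L) > 0L & !seen)
      seen[nxt] <- TRUE; frontier <- nxt
    }
    all(seen)
  }
  which(vapply(seq_len(V), function(v) {
    !connected(adj[-v, -v, drop = FALSE])
  }, logical(1L)))
}

# independent component oracle for the substructure search: union-find over
# the symmetric interaction relation
uf_components <- function(s, imap) {
  ids <- s$subchains$id
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (x in seq_along(ids)) {
    for (y in match(imap[[ids[x]]], ids)) {
      rx <- find(x); ry <- find(y)
      if (rx != ry) parent[rx] <- ry
    }
  }
  comps <- split(ids, vapply(seq_along(ids), find, integer(1L)))
  sort(unname(vapply(comps, function(m) paste(sort(m), collapse = ","),
                     character(1L))), method = "radix")
}

member_key <- function(subs) {
  sort(vapply(subs, function(x) paste(x$members, collapse = ","), character(1L)),
       method = "radix")
}
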