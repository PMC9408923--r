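# Dual-graph catalog: exhaustive enumeration of the loopless connected
# multigraphs that a single nucleic-acid strand can realize, identifier
# assignment by ascending Laplacian spectrum, and certificate-based matching.
#
# Membership rule (realizability): max degree <= 4; the number of odd-degree
# vertices is 0 or 2; and if 0, at least one vertex has degree < 4. These are
# exactly the connected multigraphs that admit a double-occurrence strand
# word (each stem traversed twice, two strand ends, hairpins absorbing spare
# slots), which is also why structure-derived graphs obey the slot bound
# deg(v) + 2*self_loops(v) <= 4.

.rnadual_cache <- new.env(parent = emptyenv())

#' Maximum vertex count supported by the catalog machinery
#' @export
MAX_CATALOG_VERTICES <- 7L

# --- skeleton generation ----------------------------------------------------

# Connected simple graphs with max degree <= 4 on V vertices, one adjacency
# matrix per isomorphism class. Built by vertex augmentation: every connected
# graph on V vertices arises from a connected graph on V-1 vertices by adding
# a vertex joined to a nonempty set of others (every connected graph has a
# non-cut vertex).
skeletons <- function(V) {
  key <- paste0("skel", V)
  if (!is.null(.rnadual_cache[[key]])) return(.rnadual_cache[[key]])
  if (V == 1L) {
    out <- list(matrix(0L, 1L, 1L))
  } else {
    parents <- skeletons(V - 1L)
    seen <- new.env(parent = emptyenv())
    out <- list()
    for (par in parents) {
      free <- which(colSums(par) < 4L)
      for (sz in seq_len(min(4L, length(free)))) {
        combos <- utils::combn(free, sz, simplify = FALSE)
        for (S in combos) {
          adj <- rbind(cbind(par, 0L), 0L)
          adj[V, S] <- 1L
          adj[S, V] <- 1L
          cert <- canonical_certificate(adj)
          if (is.null(seen[[cert]])) {
            seen[[cert]] <- TRUE
            out[[length(out) + 1L]] <- canonical_adj(adj)
          }
        }
      }
    }
  }
  .rnadual_cache[[key]] <- out
  out
}

# --- rule R -----------------------------------------------------------------

#' Does a loopless connected multigraph satisfy the realizability rule?
#'
#' @param adj symmetric integer multiplicity matrix
#' @return logical: max degree <= 4, odd-degree vertex count in {0, 2}, and if
#'   0 odd vertices, at least one vertex of degree < 4
#' @export
satisfies_realizability_rule <- function(adj) {
  deg <- as.integer(rowSums(adj))
  if (any(deg > 4L)) return(FALSE)
  odd <- sum(deg %% 2L == 1L)
  if (!odd %in% c(0L, 2L)) return(FALSE)
  if (odd == 0L && !any(deg < 4L)) return(FALSE)
  TRUE
}

# --- enumeration ------------------------------------------------------------

#' Enumerate the dual-graph catalog for a fixed vertex count
#'
#' Exhaustively generates all non-isomorphic loopless connected multigraphs on
#' `V` vertices satisfying the realizability rule, computes their Laplacian
#' spectra, and assigns identifiers `V_n` in ascending spectral order (full
#' spectrum compared lexicographically, Fiedler value first; residual exactly
#' cospectral ties broken by canonical certificate).
#'
#' @param V vertex count, 1..7
#' @param pseudoknots label each entry pseudoknotted/unknotted via the
#'   realization-word search (exact for V <= 6). Default: on for V <= 5.
#' @return object of class `dual_catalog`: a data.frame `entries` with columns
#'   `id`, `V`, `n`, `fiedler`, `spectrum`, `edges`, `certificate`,
#'   `pseudoknotted`, plus the list `adj` of canonical adjacency matrices.
#' @export
enumerate_catalog <- function(V, pseudoknots = V <= 5L) {
  if (!is.numeric(V) || length(V) != 1L || V < 1L || V > MAX_CATALOG_VERTICES) {
    stop(sprintf("V must be between 1 and %d", MAX_CATALOG_VERTICES))
  }
  V <- as.integer(V)
  key <- paste0("cat", V, if (pseudoknots) "p" else "")
  if (!is.null(.rnadual_cache[[key]])) return(.rnadual_cache[[key]])
  mats <- list()
  if (V == 1L) {
    mats <- list(matrix(0L, 1L, 1L))
  } else {
    for (sk in skeletons(V)) {
      edges <- which(upper.tri(sk) & sk == 1L, arr.ind = TRUE)
      ne <- nrow(edges)
      auts <- automorphism_perms(sk)
      # edge index permutation induced by each skeleton automorphism
      eidx <- matrix(0L, V, V)
      eidx[edges] <- seq_len(ne); eidx <- eidx + t(eidx)
      edge_perm <- lapply(auts, function(p) {
        inv <- integer(V); inv[p] <- seq_len(V)
        eidx[cbind(inv[edges[, 1L]], inv[edges[, 2L]])]
      })
      # DFS over multiplicities 1..4 per skeleton edge, degree-capped
      deg <- integer(V)
      mult <- integer(ne)
      base_deg <- as.integer(colSums(sk))  # remaining unassigned edges count
      recurse <- function(e, deg) {
        if (e > ne) {
          if (!satisfies_realizability_rule_deg(deg)) return()
          # lex-min over the automorphism orbit of the multiplicity vector
          key_self <- paste(mult, collapse = ",")
          for (ep in edge_perm) {
            if (paste(mult[ep], collapse = ",") < key_self) return()
          }
          adj <- matrix(0L, V, V)
          adj[edges] <- mult
          adj <- adj + t(adj)
          mats[[length(mats) + 1L]] <<- adj
          return()
        }
        u <- edges[e, 1L]; v <- edges[e, 2L]
        # each remaining edge needs multiplicity >= 1
        rem_u <- sum(edges[e:ne, 1L] == u | edges[e:ne, 2L] == u) - 1L
        rem_v <- sum(edges[e:ne, 1L] == v | edges[e:ne, 2L] == v) - 1L
        for (m in 1:4) {
          du <- deg[u] + m; dv <- deg[v] + m
          if (du + rem_u > 4L || dv + rem_v > 4L) break
          mult[e] <<- m
          d2 <- deg; d2[u] <- du; d2[v] <- dv
          recurse(e + 1L, d2)
        }
      }
      recurse(1L, deg)
    }
  }
  # spectra and ordering
  specs <- t(vapply(mats, laplacian_spectrum_values, numeric(V)))
  certs <- vapply(mats, canonical_certificate, character(1L))
  ord <- do.call(order, c(lapply(seq_len(V), function(k) specs[, k]), list(certs)))
  mats <- mats[ord]; specs <- specs[ord, , drop = FALSE]; certs <- certs[ord]
  n <- length(mats)
  entries <- data.frame(
    id = paste0(V, "_", seq_len(n)),
    V = V, n = seq_len(n),
    fiedler = if (V >= 2L) specs[, 2L] else rep(0, n),
    spectrum = apply(specs, 1L, function(x) paste(format(x, trim = TRUE), collapse = ",")),
    edges = vapply(mats, format_edges, character(1L)),
    certificate = certs,
    pseudoknotted = NA,
    stringsAsFactors = FALSE
  )
  if (pseudoknots) {
    if (V <= 6L) {
      entries$pseudoknotted <- vapply(mats, is_pseudoknotted_adj, logical(1L))
    }
  }
  cat_obj <- structure(list(V = V, entries = entries, adj = mats,
                            lookup = stats::setNames(seq_len(n), certs)),
                       class = "dual_catalog")
  .rnadual_cache[[key]] <- cat_obj
  # a pseudoknot-labelled catalog also serves requests without labels
  if (pseudoknots) .rnadual_cache[[paste0("cat", V)]] <- cat_obj
  cat_obj
}

satisfies_realizability_rule_deg <- function(deg) {
  odd <- sum(deg %% 2L == 1L)
  if (!odd %in% c(0L, 2L)) return(FALSE)
  if (odd == 0L && !any(deg < 4L)) return(FALSE)
  TRUE
}

#' @export
print.dual_catalog <- function(x, ...) {
  pk <- x$entries$pseudoknotted
  cat(sprintf("<dual_catalog V=%d: %d graphs%s>\n", x$V, nrow(x$entries),
              if (!anyNA(pk)) sprintf(", %d pseudoknotted", sum(pk)) else ""))
  invisible(x)
}

#' Build catalogs for vertex counts 1..v_max
#'
#' @param v_max largest vertex count (<= 7)
#' @param pseudoknots passed through to [enumerate_catalog()]
#' @return list of `dual_catalog` indexed by vertex count, class
#'   `dual_catalog_set`
#' @export
catalog_set <- function(v_max = 5L, pseudoknots = TRUE) {
  out <- lapply(seq_len(v_max), function(v) {
    enumerate_catalog(v, pseudoknots = pseudoknots && v <= 6L)
  })
  structure(out, class = "dual_catalog_set")
}

#' Fetch the catalog for one vertex count out of a catalog or catalog set
#' @noRd
catalog_for <- function(catalog, V) {
  if (inherits(catalog, "dual_catalog")) {
    if (catalog$V == V) return(catalog) else return(NULL)
  }
  if (inherits(catalog, "dual_catalog_set")) {
    if (V <= length(catalog)) return(catalog[[V]]) else return(NULL)
  }
  NULL
}

# --- spectra ----------------------------------------------------------------

laplacian_spectrum_values <- function(adj, digits = 10L) {
  L <- diag(rowSums(adj), nrow(adj)) - adj
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  round(ev, digits)
}

#' Laplacian spectrum key of a connected loopless multigraph
#'
#' Eigenvalues of L = D - A (A the integer multiplicity matrix), ascending,
#' rounded to `digits` decimal places. The second entry is the Fiedler value.
#'
#' @param g a `dual_graph` or multiplicity matrix (self-loops ignored)
#' @param digits rounding applied before comparisons
#' @return numeric vector of length V
#' @export
laplacian_spectrum_key <- function(g, digits = 10L) {
  adj <- if (inherits(g, "dual_graph")) g$edge_mult else as.matrix(g)
  if (nrow(adj) >= 2L && !is_connected_adj(adj)) {
    integrity_error("Laplacian spectrum key requires a connected graph")
  }
  laplacian_spectrum_values(adj, digits)
}

is_connected_adj <- function(adj) {
  V <- nrow(adj)
  if (V <= 1L) return(TRUE)
  seen <- logical(V); seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE] > 0L) > 0L & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Assign catalog identifiers to an exhaustive entry list
#'
#' Sort key: the full Laplacian spectrum compared lexicographically (ascending
#' Fiedler value first, later eigenvalues breaking Fiedler ties), residual
#' exactly cospectral ties broken by canonical certificate; `n` is the 1-based
#' rank. [enumerate_catalog()] applies this automatically; the function is
#' exposed for use on externally supplied graph lists.
#'
#' @param mats list of multiplicity matrices, all with the same vertex count
#' @return data.frame with `id`, `n`, `fiedler`, `certificate` in sorted order
#' @export
assign_catalog_ids <- function(mats) {
  V <- nrow(mats[[1L]])
  specs <- t(vapply(mats, laplacian_spectrum_values, numeric(V)))
  certs <- vapply(mats, canonical_certificate, character(1L))
  ord <- do.call(order, c(lapply(seq_len(V), function(k) specs[, k]), list(certs)))
  data.frame(id = paste0(V, "_", seq_along(mats)),
             n = seq_along(mats),
             fiedler = if (V >= 2L) specs[ord, 2L] else rep(0, length(mats)),
             certificate = certs[ord],
             stringsAsFactors = FALSE)
}

# --- matching ---------------------------------------------------------------

#' Match a dual graph against the catalog
#'
#' Self-loops are stripped, then the canonical certificate is looked up.
#'
#' @param g a `dual_graph` or multiplicity matrix
#' @param catalog a `dual_catalog` or `dual_catalog_set`; defaults to catalogs
#'   built (and cached) on demand up to [MAX_CATALOG_VERTICES]
#' @return `"V_n"` on a hit; `"no_helices"` for the empty graph; `"unmatched
#'   (oversized)"` when V exceeds the available catalog; `"unmatched"` when no
#'   catalog entry fits (disconnected or rule-violating graphs)
#' @export
match_graph <- function(g, catalog = NULL) {
  adj <- if (inherits(g, "dual_graph")) g$edge_mult else as.matrix(g)
  V <- nrow(adj)
  if (V == 0L) return("no_helices")
  if (is.null(catalog)) {
    if (V > MAX_CATALOG_VERTICES) return("unmatched (oversized)")
    catalog <- enumerate_catalog(V, pseudoknots = FALSE)
  }
  cat_v <- catalog_for(catalog, V)
  if (is.null(cat_v)) return("unmatched (oversized)")
  hit <- cat_v$lookup[canonical_certificate(adj)]
  if (is.na(hit)) return("unmatched")
  cat_v$entries$id[hit]
}

#' Look up a catalog entry by id
#' @param catalog a `dual_catalog` or `dual_catalog_set`
#' @param id identifier like `"3_5"`
#' @return list with `entry` (one-row data.frame) and `adj`
#' @export
catalog_entry <- function(catalog, id) {
  V <- as.integer(sub("_.*", "", id))
  cat_v <- catalog_for(catalog, V)
  if (is.null(cat_v)) stop(sprintf("no catalog for V=%d", V))
  row <- match(id, cat_v$entries$id)
  if (is.na(row)) stop(sprintf("no catalog entry '%s'", id))
  list(entry = cat_v$entries[row, ], adj = cat_v$adj[[row]])
}

# --- pseudoknot oracles -----------------------------------------------------

# Depth-first search for a strand word realizing `adj`.
# A word lists each vertex exactly twice; each adjacent letter pair (u, v)
# with u != v consumes one copy of edge (u, v); adjacent equal letters are
# hairpins and consume nothing. `noncrossing = TRUE` restricts the search to
# stack-discipline words (the chord diagram of the two occurrences of each
# vertex has no crossing), which is the unknotted case.
find_realization_word <- function(adj, noncrossing) {
  V <- nrow(adj)
  if (V == 0L) return(integer(0))
  total <- sum(adj) / 2L
  found <- NULL
  counts <- integer(V)
  word <- integer(2L * V)
  rem <- adj
  search <- function(pos, stack, remaining) {
    if (!is.null(found)) return()
    if (pos > 2L * V) {
      if (remaining == 0L) found <<- word[seq_len(2L * V)]
      return()
    }
    prev <- if (pos > 1L) word[pos - 1L] else 0L
    step <- function(v) {
      if (!is.null(found)) return()
      consume <- prev != 0L && prev != v
      if (consume && rem[prev, v] < 1L) return()
      if (consume) { rem[prev, v] <<- rem[prev, v] - 1L; rem[v, prev] <<- rem[v, prev] - 1L }
      word[pos] <<- v
      counts[v] <<- counts[v] + 1L
      if (noncrossing) {
        new_stack <- if (counts[v] == 1L) c(stack, v) else stack[-length(stack)]
      } else new_stack <- stack
      search(pos + 1L, new_stack, remaining - consume)
      counts[v] <<- counts[v] - 1L
      if (consume) { rem[prev, v] <<- rem[prev, v] + 1L; rem[v, prev] <<- rem[v, prev] + 1L }
    }
    if (noncrossing) {
      # close the top of the stack, or open any unopened vertex
      if (length(stack)) step(stack[length(stack)])
      for (v in which(counts == 0L)) step(v)
    } else {
      for (v in which(counts < 2L)) step(v)
    }
  }
  search(1L, integer(0), total)
  found
}

#' Is a catalog graph pseudoknotted?
#'
#' A graph is pseudoknotted when no single-strand realization word yields a
#' noncrossing chord diagram: every strand that folds into this topology must
#' contain crossing base pairs. Exact search, memoised per certificate.
#'
#' @param e a catalog entry (from [catalog_entry()]), a `dual_graph`, or a
#'   multiplicity matrix; self-loops are ignored
#' @return logical, or `NA` when V exceeds the exact search bound (6)
#' @export
is_pseudoknotted_graph <- function(e) {
  adj <- if (is.list(e) && !is.null(e$adj)) e$adj
  else if (inherits(e, "dual_graph")) e$edge_mult
  else as.matrix(e)
  if (nrow(adj) > 6L) return(NA)
  is_pseudoknotted_adj(adj)
}

is_pseudoknotted_adj <- function(adj) {
  cert <- canonical_certificate(adj)
  key <- paste0("pk", cert)
  hit <- .rnadual_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- is.null(find_realization_word(adj, noncrossing = TRUE))
  .rnadual_cache[[key]] <- res
  res
}

#' Does any single-strand realization word exist? (rule-R cross-check)
#' @param adj multiplicity matrix
#' @return logical
#' @export
has_single_strand_realization <- function(adj) {
  !is.null(find_realization_word(as.matrix(adj), noncrossing = FALSE))
}

# --- nested-forest oracle ---------------------------------------------------

# Ordered rooted forests with n nodes (trees as nested lists of child trees).
ordered_forests <- function(n) {
  key <- paste0("forest", n)
  if (!is.null(.rnadual_cache[[key]])) return(.rnadual_cache[[key]])
  out <- if (n == 0L) list(list()) else {
    acc <- list()
    for (k in seq_len(n)) {             # k nodes in the first tree
      for (tree_children in ordered_forests(k - 1L)) {
        for (rest in ordered_forests(n - k)) {
          acc[[length(acc) + 1L]] <- c(list(tree_children), rest)
        }
      }
    }
    acc
  }
  .rnadual_cache[[key]] <- out
  out
}

forest_to_adj <- function(forest, n) {
  adj <- matrix(0L, n, n)
  counter <- 0L
  add <- function(u, v) { adj[u, v] <<- adj[u, v] + 1L; adj[v, u] <<- adj[v, u] + 1L }
  walk <- function(children) {
    counter <<- counter + 1L
    me <- counter
    ids <- vapply(children, walk, integer(1L))
    if (length(ids) == 1L) {
      add(me, ids)          # internal loop: double edge to the sole child
      add(me, ids)
    } else if (length(ids) >= 2L) {
      add(me, ids[1L])      # junction cycle parent -> C1 -> ... -> Ck -> parent
      for (k in seq_len(length(ids) - 1L)) add(ids[k], ids[k + 1L])
      add(ids[length(ids)], me)
    }
    me
  }
  roots <- vapply(forest, walk, integer(1L))
  if (length(roots) >= 2L) {
    for (k in seq_len(length(roots) - 1L)) add(roots[k], roots[k + 1L])
  }
  adj
}

#' Catalog ids realizable by fully nested (unknotted) structures
#'
#' Independent oracle: enumerate all ordered rooted forests with `V` stem
#' nodes, map each to its dual graph (a sole child gives a double edge to the
#' parent; k >= 2 children give the junction cycle parent, C1, ..., Ck,
#' parent; consecutive roots are joined by unit edges), and collect the
#' catalog ids that arise. The complement within the catalog is the
#' pseudoknotted set.
#'
#' @param V vertex count (<= 5 recommended; forest count grows as Catalan(V))
#' @param catalog optional prebuilt catalog for `V`
#' @return sorted character vector of ids
#' @export
nested_unknotted_set <- function(V, catalog = NULL) {
  if (is.null(catalog)) catalog <- enumerate_catalog(V, pseudoknots = FALSE)
  ids <- unique(vapply(ordered_forests(V), function(f) {
    match_graph(forest_to_adj(f, V), catalog)
  }, character(1L)))
  sort(ids)
}

#' Write a catalog as TSV text
#' @param catalog a `dual_catalog` or `dual_catalog_set`
#' @return TSV text with columns id, V, n, edges, fiedler, spectrum, pseudoknotted
#' @export
write_catalog_tsv <- function(catalog) {
  cats <- if (inherits(catalog, "dual_catalog")) list(catalog) else catalog
  df <- do.call(rbind, lapply(cats, function(x)
    x$entries[, c("id", "V", "n", "edges", "fiedler", "spectrum", "pseudoknotted")]))
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}
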