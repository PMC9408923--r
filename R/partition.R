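# Partitioning a dual graph into blocks at articulation points.
#
# Removing an articulation point disconnects the graph; the maximal
# biconnected subgraphs between articulation points are the blocks. Parallel
# edges make their endpoints mutually biconnected, so pseudoknots (multi-edge
# intertwinings) and junction cycles always stay inside one block, which is
# what makes the partition biologically meaningful. Self-loops (hairpins) are
# recorded as annotations on their vertex and never enter blocks.

dual_to_igraph <- function(adj) {
  idx <- which(upper.tri(adj) & adj > 0L, arr.ind = TRUE)
  if (!nrow(idx)) return(igraph::make_empty_graph(nrow(adj), directed = FALSE))
  el <- idx[rep(seq_len(nrow(idx)), adj[idx]), , drop = FALSE]
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < nrow(adj)) {
    g <- igraph::add_vertices(g, nrow(adj) - igraph::vcount(g))
  }
  g
}

#' Articulation points of a dual graph
#'
#' @param g a `dual_graph` or multiplicity matrix (self-loops ignored);
#'   must be connected
#' @return integer vector of articulation vertices (possibly empty)
#' @export
find_articulation_points <- function(g) {
  adj <- if (inherits(g, "dual_graph")) g$edge_mult else as.matrix(g)
  if (nrow(adj) >= 2L && !is_connected_adj(adj)) {
    integrity_error("articulation points are defined for connected graphs")
  }
  if (nrow(adj) <= 2L || sum(adj) == 0L) return(integer(0))
  sort(as.integer(igraph::articulation_points(dual_to_igraph(adj))))
}

#' Block decomposition of a dual graph
#'
#' @param g a `dual_graph` or multiplicity matrix; self-loops are stripped
#'   and reported as per-vertex annotations
#' @return object of class `block_decomposition`: `articulation_points`,
#'   `blocks` (list of `list(vertices, adj, graph_id)` in original vertex
#'   numbering), `block_adjacency` (logical matrix: blocks sharing an
#'   articulation point), `self_loop_annotations`, `graph_id` of the full
#'   graph, and `adj` of the input
#' @param catalog catalog (set) used to label blocks; built on demand if NULL
#' @export
block_decomposition <- function(g, catalog = NULL) {
  adj <- if (inherits(g, "dual_graph")) g$edge_mult else as.matrix(g)
  sl <- if (inherits(g, "dual_graph")) g$self_loops else integer(nrow(adj))
  V <- nrow(adj)
  aps <- find_articulation_points(adj)
  if (V == 1L || sum(adj) == 0L) {
    blocks <- list()
  } else {
    ig <- dual_to_igraph(adj)
    bc <- igraph::biconnected_components(ig)
    blocks <- lapply(bc$components, function(vs) {
      verts <- sort(as.integer(vs))
      sub <- adj[verts, verts, drop = FALSE]
      list(vertices = verts, adj = sub, graph_id = match_graph(sub, catalog))
    })
    blocks <- blocks[order(vapply(blocks, function(b) min(b$vertices), integer(1L)),
                           vapply(blocks, function(b) length(b$vertices), integer(1L)))]
  }
  nb <- length(blocks)
  badj <- matrix(FALSE, nb, nb)
  if (nb >= 2L) {
    for (a in seq_len(nb - 1L)) {
      for (b in (a + 1L):nb) {
        badj[a, b] <- badj[b, a] <-
          length(intersect(blocks[[a]]$vertices, blocks[[b]]$vertices)) > 0L
      }
    }
  }
  structure(list(adj = adj, articulation_points = aps, blocks = blocks,
                 block_adjacency = badj,
                 self_loop_annotations = which(sl > 0L),
                 graph_id = match_graph(adj, catalog)),
            class = "block_decomposition")
}

#' @export
print.block_decomposition <- function(x, ...) {
  cat(sprintf("<block_decomposition of %s: %d articulation point(s), blocks: %s>\n",
              x$graph_id, length(x$articulation_points),
              paste(vapply(x$blocks, function(b) b$graph_id, character(1L)),
                    collapse = ", ")))
  invisible(x)
}

#' Merged-block subgraph inventory
#'
#' One record per connected set of blocks in the block-cut tree — single
#' blocks, merged adjacent blocks (blocks sharing an articulation point), up
#' to the full graph — filtered to subgraphs of `2..max_vertices` vertices
#' and matched against the catalog.
#'
#' @param d a `block_decomposition`
#' @param max_vertices upper vertex bound for reported subgraphs (default 9)
#' @param catalog catalog (set) for matching
#' @param max_records cap on the number of block subsets explored; exceeding
#'   it truncates with a warning
#' @return data.frame with columns `kind` (`block`/`merged`/`full`),
#'   `vertex_set`, `n_vertices`, `block_ids`, `graph_id`
#' @export
merged_subgraphs <- function(d, max_vertices = 9L, catalog = NULL,
                             max_records = 4096L) {
  nb <- length(d$blocks)
  if (nb == 0L) {
    return(data.frame(kind = character(0), vertex_set = character(0),
                      n_vertices = integer(0), block_ids = character(0),
                      graph_id = character(0), stringsAsFactors = FALSE))
  }
  subsets <- list()
  # enumerate nonempty block subsets, keeping only those connected in the
  # block adjacency graph
  total <- 2^nb - 1L
  if (total > max_records) {
    warning(sprintf("block subset count %d exceeds cap %d; truncating", total,
                    max_records))
  }
  for (mask in seq_len(min(total, max_records))) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(nb) - 1L)) > 0L)
    if (length(sel) > 1L && !blocks_connected(d$block_adjacency, sel)) next
    subsets[[length(subsets) + 1L]] <- sel
  }
  rows <- lapply(subsets, function(sel) {
    verts <- sort(unique(unlist(lapply(d$blocks[sel], function(b) b$vertices))))
    if (length(verts) < 2L || length(verts) > max_vertices) return(NULL)
    sub <- matrix(0L, length(verts), length(verts))
    for (b in d$blocks[sel]) {
      at <- match(b$vertices, verts)
      sub[at, at] <- sub[at, at] + b$adj
    }
    kind <- if (length(sel) == nb) "full"
    else if (length(sel) == 1L) "block" else "merged"
    data.frame(kind = kind,
               vertex_set = paste(verts, collapse = ","),
               n_vertices = length(verts),
               block_ids = paste(sort(sel), collapse = "+"),
               graph_id = match_graph(sub, catalog),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(kind = character(0), vertex_set = character(0),
                      n_vertices = integer(0), block_ids = character(0),
                      graph_id = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df[order(df$n_vertices, df$vertex_set), , drop = FALSE]
}

blocks_connected <- function(badj, sel) {
  seen <- sel[1L]
  repeat {
    nxt <- sel[sel %in% which(colSums(badj[seen, , drop = FALSE]) > 0L)]
    nxt <- setdiff(nxt, seen)
    if (!length(nxt)) break
    seen <- c(seen, nxt)
  }
  length(seen) == length(sel)
}

#' Subgraph census over substructures
#'
#' The weight of a subgraph id is the number of substructures containing it at
#' least once among their blocks and merged blocks (per-substructure
#' deduplication by default; `count_occurrences = TRUE` counts every distinct
#' vertex set instead). Categories are split as in [motif_census()].
#'
#' @param subs list of `substructure` objects (those with >= 2 helices
#'   contribute)
#' @param catalog catalog (set) for matching
#' @param max_vertices passed to [merged_subgraphs()]
#' @param count_occurrences switch between substructure counting and
#'   occurrence counting
#' @return data.frame like [motif_census()] without example names
#' @export
subgraph_census <- function(subs, catalog = NULL, max_vertices = 9L,
                            count_occurrences = FALSE) {
  tallies <- list()
  for (sub in subs) {
    if (sub$helix_count < 2L) next
    d <- block_decomposition(strip_self_loops(sub$graph), catalog = catalog)
    ms <- merged_subgraphs(d, max_vertices = max_vertices, catalog = catalog)
    ids <- ms$graph_id
    if (!count_occurrences) ids <- unique(ids)
    for (id in ids) {
      tallies[[length(tallies) + 1L]] <- c(id = id, cat = sub$category)
    }
  }
  if (!length(tallies)) {
    return(data.frame(graph_id = character(0), V = integer(0), n = integer(0),
                      weight = integer(0), count_single_rna = integer(0),
                      count_multi_rna = integer(0), count_dna = integer(0),
                      stringsAsFactors = FALSE))
  }
  tal <- as.data.frame(do.call(rbind, tallies), stringsAsFactors = FALSE)
  rows <- lapply(unique(tal$id), function(id) {
    sel <- tal$id == id
    data.frame(graph_id = id,
               V = ifelse(grepl("^[0-9]+_", id), as.integer(sub("_.*", "", id)), NA),
               n = ifelse(grepl("^[0-9]+_", id), id_index(id), NA),
               weight = sum(sel),
               count_single_rna = sum(sel & tal$cat == "single_rna_subchain"),
               count_multi_rna = sum(sel & tal$cat == "multiple_rna_subchains"),
               count_dna = sum(sel & tal$cat == "dna_containing"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df[order(is.na(df$V), df$V, df$n, df$graph_id), , drop = FALSE]
}
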