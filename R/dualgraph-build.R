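# Stem detection and dual-graph construction.
#
# Representation rules: a stem of >= 2 stacked base pairs is a vertex;
# junction loops, pseudoknot strands and each side of an internal loop/bulge
# are edges; hairpin loops are self-edges; 1-nt bulges and 1x1 internal loops
# are absorbed into the enclosing stem; isolated single base pairs and the
# dangling 5'/3' ends are ignored.

#' Find helical stems of a structure
#'
#' Maximal runs of stacked base pairs ((i,j),(i+1,j-1), both steps staying
#' inside one subchain per strand) are located first. Runs separated only by a
#' 1-nt bulge on one strand, or by a 1-nt/1-nt internal loop, are then merged
#' iteratively to a fixed point; the gap residues must be unpaired and on the
#' same subchain. After merging, stems with fewer than 2 base pairs are
#' discarded (isolated pairs) and their residues count as unpaired.
#'
#' @param s a [complex_structure()]
#' @return list of stems; each stem is a list with `id`, `pairs` (matrix of
#'   global positions, 5' side ascending), and `side1`/`side2` spans
#'   `c(subchain_row, start, end)` in global positions.
#' @export
find_stems <- function(s) {
  P <- s$pairs
  if (!nrow(P)) return(list())
  subof <- rep(seq_len(nrow(s$subchains)),
               s$subchains$end - s$subchains$start + 1L)
  partner <- partner_vector(s)
  ord <- order(P[, 1L])
  P <- P[ord, , drop = FALSE]
  # maximal stacked runs
  runs <- list()
  cur <- NULL
  for (r in seq_len(nrow(P))) {
    i <- P[r, 1L]; j <- P[r, 2L]
    if (!is.null(cur)) {
      li <- cur[nrow(cur), 1L]; lj <- cur[nrow(cur), 2L]
      stacked <- (i == li + 1L) && (j == lj - 1L) &&
        subof[i] == subof[li] && subof[j] == subof[lj]
      if (stacked) {
        cur <- rbind(cur, c(i, j))
        next
      }
      runs[[length(runs) + 1L]] <- cur
    }
    cur <- matrix(c(i, j), ncol = 2L)
  }
  if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
  # iterative small-loop merging
  repeat {
    merged <- FALSE
    if (length(runs) >= 2L) {
      for (x in seq_along(runs)) {
        for (y in seq_along(runs)) {
          if (x == y) next
          X <- runs[[x]]; Y <- runs[[y]]
          xi <- X[nrow(X), 1L]; xj <- X[nrow(X), 2L]  # innermost pair of X
          yi <- Y[1L, 1L]; yj <- Y[1L, 2L]            # outermost pair of Y
          g5 <- yi - xi - 1L
          g3 <- xj - yj - 1L
          if (g5 < 0L || g3 < 0L || g5 > 1L || g3 > 1L) next
          if (subof[xi] != subof[yi] || subof[yj] != subof[xj]) next
          gap_pos <- c(if (g5 == 1L) xi + 1L, if (g3 == 1L) yj + 1L)
          if (any(partner[gap_pos] > 0L)) next
          runs[[x]] <- rbind(X, Y)
          runs[[y]] <- NULL
          merged <- TRUE
          break
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  runs <- Filter(function(m) nrow(m) >= 2L, runs)
  if (!length(runs)) return(list())
  # stable order by outermost 5' position
  runs <- runs[order(vapply(runs, function(m) m[1L, 1L], integer(1L)))]
  lapply(seq_along(runs), function(k) {
    m <- runs[[k]]
    list(id = k, pairs = m,
         side1 = c(sub = subof[m[1L, 1L]], start = min(m[, 1L]), end = max(m[, 1L])),
         side2 = c(sub = subof[m[1L, 2L]], start = min(m[, 2L]), end = max(m[, 2L])))
  })
}

#' Per-subchain traversal order of stem side intervals
#'
#' For every subchain, the stem side intervals it hosts, sorted 5' to 3'.
#' Each stem contributes exactly two intervals across all subchains.
#'
#' @param s a [complex_structure()]
#' @param stems result of [find_stems()]
#' @return list with one data.frame per subchain (columns `stem`, `start`,
#'   `end`), named by subchain id
#' @export
traversal_visits <- function(s, stems = find_stems(s)) {
  nsub <- nrow(s$subchains)
  out <- vector("list", nsub)
  names(out) <- s$subchains$id
  empty <- data.frame(stem = integer(0), start = integer(0), end = integer(0))
  for (k in seq_len(nsub)) out[[k]] <- empty
  for (st in stems) {
    for (side in list(st$side1, st$side2)) {
      k <- side[["sub"]]
      out[[k]] <- rbind(out[[k]],
                        data.frame(stem = st$id, start = side[["start"]],
                                   end = side[["end"]]))
    }
  }
  for (k in seq_len(nsub)) {
    v <- out[[k]]
    if (nrow(v) > 1L) {
      v <- v[order(v$start), , drop = FALSE]
      if (any(v$start[-1L] <= v$end[-nrow(v)])) {
        integrity_error("overlapping stem intervals on one subchain")
      }
    }
    rownames(v) <- NULL
    out[[k]] <- v
  }
  out
}

#' Build the dual graph of a structure
#'
#' Stems become vertices. Walking each subchain 5' to 3', every pair of
#' consecutive stem visits adds one edge between the two stems (a self-loop
#' when both visits belong to the same stem, i.e. a hairpin). Zero-length
#' segments between visits (the strand opposite a bulge) still contribute an
#' edge, so an internal loop or bulge yields two parallel edges. Segments
#' before the first and after the last visit of a subchain (dangling ends)
#' contribute nothing. A structure without stems yields the empty graph
#' (`n_vertices` 0), flagged by downstream matching as `"no_helices"`.
#'
#' @param s a [complex_structure()]
#' @param stems optionally precomputed [find_stems()] output
#' @return object of class `dual_graph`: `n_vertices`, `edge_mult` (symmetric
#'   integer matrix, zero diagonal), `self_loops` (integer vector), `stems`,
#'   `visits`, `provenance` (one of `"single_rna_subchain"`,
#'   `"multiple_rna_subchains"`, `"dna_containing"`).
#' @export
build_dual_graph <- function(s, stems = find_stems(s)) {
  V <- length(stems)
  visits <- traversal_visits(s, stems)
  em <- matrix(0L, V, V)
  sl <- integer(V)
  for (v in visits) {
    if (nrow(v) < 2L) next
    for (r in seq_len(nrow(v) - 1L)) {
      a <- v$stem[r]; b <- v$stem[r + 1L]
      if (a == b) sl[a] <- sl[a] + 1L
      else {
        em[a, b] <- em[a, b] + 1L
        em[b, a] <- em[b, a] + 1L
      }
    }
  }
  prov <- if (any(s$subchains$molecule == "DNA")) "dna_containing"
  else if (nrow(s$subchains) == 1L) "single_rna_subchain"
  else "multiple_rna_subchains"
  structure(list(n_vertices = V, edge_mult = em, self_loops = sl,
                 stems = stems, visits = visits, provenance = prov,
                 name = s$name),
            class = "dual_graph")
}

#' Construct a dual graph directly from an edge multiplicity matrix
#'
#' Convenience constructor for catalog-style graphs that did not come from a
#' structure.
#' @param edge_mult symmetric integer matrix with zero diagonal
#' @param self_loops integer vector of hairpin counts per vertex
#' @param name graph name
#' @export
dual_graph <- function(edge_mult, self_loops = integer(nrow(edge_mult)),
                       name = "graph") {
  edge_mult <- as.matrix(edge_mult)
  storage.mode(edge_mult) <- "integer"
  if (nrow(edge_mult) != ncol(edge_mult) || any(edge_mult != t(edge_mult)) ||
      any(diag(edge_mult) != 0L)) {
    integrity_error("edge_mult must be symmetric with zero diagonal")
  }
  structure(list(n_vertices = nrow(edge_mult), edge_mult = edge_mult,
                 self_loops = as.integer(self_loops), stems = NULL,
                 visits = NULL, provenance = NA_character_, name = name),
            class = "dual_graph")
}

#' @export
print.dual_graph <- function(x, ...) {
  cat(sprintf("<dual_graph '%s': V=%d, edges=%d, self-loops=%d (%s)>\n",
              x$name, x$n_vertices, sum(x$edge_mult) / 2L, sum(x$self_loops),
              format_edges(x$edge_mult)))
  invisible(x)
}

#' Compact "u-v:m" edge listing of a multiplicity matrix
#' @noRd
format_edges <- function(em) {
  if (!nrow(em)) return("empty")
  idx <- which(upper.tri(em) & em > 0L, arr.ind = TRUE)
  if (!nrow(idx)) return("no edges")
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  paste(sprintf("%d-%d:%d", idx[, 1L], idx[, 2L], em[idx]), collapse = ";")
}

#' Total degree (edge multiplicities, self-loops counted twice)
#' @param g a `dual_graph`
#' @return integer vector of per-vertex slot loads `deg(v) + 2*self_loops(v)`
#' @export
slot_load <- function(g) {
  if (!g$n_vertices) return(integer(0))
  as.integer(rowSums(g$edge_mult)) + 2L * g$self_loops
}

#' Strip self-loops (hairpins) from a dual graph
#'
#' Catalog matching and partitioning operate on the loopless graph.
#' @param g a `dual_graph`
#' @return the same graph with `self_loops` zeroed
#' @export
strip_self_loops <- function(g) {
  g$self_loops <- integer(g$n_vertices)
  g
}
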