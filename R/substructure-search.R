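# Grouping interacting subchains into independently folded substructures.
#
# Two subchains interact when they share more than one base pair; pairs of
# near-identical subchains (>92% sequence AND >92% 2D-structure identity) are
# excluded from the interaction relation to avoid crystallographic polymers.
# Substructures are the closures of the interaction relation; each receives
# one dual graph. Substructures with more than 9 helices can be refined in a
# second round using representative-chain filter groups.

#' Pairwise interaction map of a structure's subchains
#'
#' `y` belongs to `Y_x` when subchains x and y share at least `min_bp` base
#' pairs and the unordered pair is not excluded by the polymer filter (both
#' sequence and structure identity above `similarity_threshold`). The map is
#' symmetric by construction.
#'
#' @param s a [complex_structure()]
#' @param min_bp minimum shared base pairs (default 2, i.e. ">1 base pairs")
#' @param similarity_threshold polymer-filter identity threshold (strict
#'   inequality; default 0.92)
#' @return named list: for each subchain id, the character vector `Y_x`
#' @export
interaction_map <- function(s, min_bp = 2L, similarity_threshold = 0.92) {
  ids <- s$subchains$id
  Y <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  P <- s$pairs
  if (!nrow(P)) return(Y)
  subof <- rep(seq_len(nrow(s$subchains)),
               s$subchains$end - s$subchains$start + 1L)
  a <- subof[P[, 1L]]; b <- subof[P[, 2L]]
  inter <- a != b
  if (!any(inter)) return(Y)
  key <- paste(pmin(a[inter], b[inter]), pmax(a[inter], b[inter]))
  counts <- table(key)
  for (k in names(counts)) {
    if (counts[[k]] < min_bp) next
    uv <- as.integer(strsplit(k, " ")[[1L]])
    sim <- chain_similarity(get_subchain(s, ids[uv[1L]]),
                            get_subchain(s, ids[uv[2L]]))
    if (sim[["seq_identity"]] > similarity_threshold &&
        sim[["struct_identity"]] > similarity_threshold) next  # polymer pair
    Y[[ids[uv[1L]]]] <- c(Y[[ids[uv[1L]]]], ids[uv[2L]])
    Y[[ids[uv[2L]]]] <- c(Y[[ids[uv[2L]]]], ids[uv[1L]])
  }
  lapply(Y, sort)
}

#' Category of a substructure
#'
#' `dna_containing` if any member subchain is DNA; otherwise
#' `single_rna_subchain` for exactly one member; otherwise
#' `multiple_rna_subchains`.
#' @param members character vector of member subchain ids
#' @param s the parent [complex_structure()]
#' @return category string
#' @export
categorize_substructure <- function(members, s) {
  mol <- s$subchains$molecule[match(members, s$subchains$id)]
  if (any(mol == "DNA")) "dna_containing"
  else if (length(members) == 1L) "single_rna_subchain"
  else "multiple_rna_subchains"
}

new_substructure <- function(s, members, catalog, origin,
                             oversize_helices = 9L) {
  sub <- restrict_structure(s, members,
                            name = paste0(s$name, ":", paste(members, collapse = "+")))
  g <- build_dual_graph(sub)
  V <- g$n_vertices
  graph_id <- if (V == 0L) "no_helices"
  else if (V > oversize_helices) "oversized"
  else match_graph(g, catalog)
  structure(list(members = sort(members), structure = sub, graph = g,
                 helix_count = V,
                 category = categorize_substructure(members, s),
                 graph_id = graph_id, origin = origin,
                 parent = s$name),
            class = "substructure")
}

#' @export
print.substructure <- function(x, ...) {
  cat(sprintf("<substructure {%s}: %s, %d helices, graph %s (%s)>\n",
              paste(x$members, collapse = ","), x$category, x$helix_count,
              x$graph_id, x$origin))
  invisible(x)
}

#' Identify independently folded substructures
#'
#' Implements the closure search: each unassigned subchain x seeds a
#' substructure with itself and `Y_x`; interacting subchains of newly added
#' members are pulled in repeatedly until no new subchain joins. Every
#' subchain ends up in exactly one substructure; subchains with no helices are
#' emitted as `"no_helices"` singletons. All base pairs among the members
#' (including single-pair contacts below the grouping threshold) are kept for
#' graph construction.
#'
#' @param s a [complex_structure()]
#' @param imap interaction map (computed from `s` if omitted)
#' @param catalog catalog (set) for graph matching; built on demand if omitted
#' @param min_bp,similarity_threshold passed to [interaction_map()]
#' @param oversize_helices substructures with more helices than this get
#'   `graph_id` `"oversized"` (default 9)
#' @return list of `substructure` objects, in order of their seed subchains
#' @export
find_substructures <- function(s, imap = NULL, catalog = NULL,
                               min_bp = 2L, similarity_threshold = 0.92,
                               oversize_helices = 9L) {
  if (is.null(imap)) {
    imap <- interaction_map(s, min_bp = min_bp,
                            similarity_threshold = similarity_threshold)
  }
  C <- s$subchains$id
  library_set <- C
  out <- list()
  for (x in C) {
    if (!x %in% library_set) next
    Sx <- union(x, imap[[x]])
    Snew <- Sx
    while (length(Snew)) {
      Stmp <- Sx
      for (z in Snew) Stmp <- union(Stmp, imap[[z]])
      Snew <- setdiff(Stmp, Sx)
      Sx <- Stmp
    }
    library_set <- setdiff(library_set, Sx)
    out[[length(out) + 1L]] <- new_substructure(s, Sx, catalog, "round1",
                                                oversize_helices)
  }
  out
}

#' Filter groups for round-2 refinement
#'
#' @param x a data.frame with columns `filter_name` and `chain_id`, a path to
#'   such a TSV, or a named list of chain-id vectors
#' @return named list of chain-id character vectors
#' @export
as_filter_groups <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("filter_name", "chain_id") %in% names(x)))
    x <- split(x$chain_id, x$filter_name)
  }
  lapply(x, as.character)
}

#' Round-2 refinement of an oversized substructure
#'
#' For each filter group (a set of representative chain ids) intersecting the
#' substructure, the member subchains whose chain belongs to the group are
#' extracted (pairs leaving the restriction are dropped) and the substructure
#' search is rerun on that restriction. Results with at most `oversize_helices`
#' helices are collected; identical member sets arising from overlapping
#' filters are deduplicated; refined groups still exceeding the bound are
#' dropped with a log record.
#'
#' @param sub an oversized `substructure`
#' @param filters anything accepted by [as_filter_groups()]
#' @param catalog catalog (set) for matching
#' @param oversize_helices helix bound (default 9)
#' @return list of `substructure` objects with `origin = "round2"`; attribute
#'   `"log"` records filters that contributed nothing and refined groups
#'   dropped for size
#' @export
refine_oversized <- function(sub, filters, catalog = NULL,
                             oversize_helices = 9L) {
  stopifnot(inherits(sub, "substructure"))
  filters <- as_filter_groups(filters)
  log <- character(0)
  out <- list()
  seen <- character(0)
  member_chains <- sub$structure$subchains$chain
  for (fname in names(filters)) {
    keep <- sub$structure$subchains$id[member_chains %in% filters[[fname]]]
    if (!length(keep)) {
      log <- c(log, sprintf("filter '%s': no member subchains", fname))
      next
    }
    restricted <- restrict_structure(sub$structure, keep,
                                     name = paste0(sub$parent, ":", fname))
    refined <- find_substructures(restricted, catalog = catalog,
                                  oversize_helices = oversize_helices)
    for (r in refined) {
      if (r$helix_count > oversize_helices) {
        log <- c(log, sprintf("filter '%s': refined group {%s} still has %d helices; dropped",
                              fname, paste(r$members, collapse = ","), r$helix_count))
        next
      }
      key <- paste(r$members, collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      r$origin <- "round2"
      out[[length(out) + 1L]] <- r
    }
  }
  if (!length(filters)) log <- c(log, "no filters supplied")
  attr(out, "log") <- log
  out
}

#' Motif census over a set of substructures
#'
#' One row per matched dual graph: the weight (number of substructures) split
#' into the three composition categories, with example structure names.
#' Unmatched, helix-free and oversized substructures are tallied in separate
#' rows at the bottom (with `V` and `n` equal to `NA`). Rows are ordered by
#' (V, n).
#'
#' @param subs list of `substructure` objects
#' @param max_examples number of example names kept per row
#' @return data.frame with columns `graph_id`, `V`, `n`, `weight`,
#'   `count_single_rna`, `count_multi_rna`, `count_dna`, `example_names`
#' @export
motif_census <- function(subs, max_examples = 3L) {
  ids <- vapply(subs, function(x) x$graph_id, character(1L))
  cats <- vapply(subs, function(x) x$category, character(1L))
  names_ <- vapply(subs, function(x) x$structure$name, character(1L))
  rows <- lapply(unique(ids), function(id) {
    sel <- ids == id
    data.frame(graph_id = id,
               V = ifelse(grepl("^[0-9]+_", id), as.integer(sub("_.*", "", id)), NA),
               n = ifelse(grepl("^[0-9]+_", id), id_index(id), NA),
               weight = sum(sel),
               count_single_rna = sum(sel & cats == "single_rna_subchain"),
               count_multi_rna = sum(sel & cats == "multiple_rna_subchains"),
               count_dna = sum(sel & cats == "dna_containing"),
               example_names = paste(utils::head(names_[sel], max_examples),
                                     collapse = ";"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df[order(is.na(df$V), df$V, df$n, df$graph_id), , drop = FALSE]
}
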