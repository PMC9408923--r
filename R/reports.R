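# Application-level tabulation: motif tables for labelled structure groups
# (frameshifting elements, riboswitches), subgraph presence matrices, and the
# log-linear growth fit of catalog/subgraph counts.

#' Motif classification table for labelled structures
#'
#' Builds the dual graph of every input structure, matches it against the
#' catalog, and reports the pseudoknot status of the matched motif. Row order
#' is input order.
#'
#' @param structures named list of [complex_structure()] objects
#' @param groups character vector of group labels, one per structure
#' @param catalog catalog (set) for matching; built on demand if NULL
#' @param annotations optional named character vector carried through verbatim
#'   (e.g. literature frameshifting efficiencies)
#' @return data.frame with columns `name`, `group`, `graph_id`,
#'   `pseudoknotted`, `annotation`
#' @export
classify_group <- function(structures, groups, catalog = NULL,
                           annotations = NULL) {
  stopifnot(length(structures) == length(groups))
  nms <- names(structures)
  if (is.null(nms)) nms <- vapply(structures, function(s) s$name, character(1L))
  rows <- lapply(seq_along(structures), function(k) {
    g <- build_dual_graph(structures[[k]])
    id <- match_graph(g, catalog)
    pk <- if (grepl("^[0-9]+_[0-9]+$", id)) {
      is_pseudoknotted_graph(strip_self_loops(g))
    } else NA
    data.frame(name = nms[k], group = groups[k], graph_id = id,
               pseudoknotted = pk,
               annotation = if (!is.null(annotations) && nms[k] %in% names(annotations))
                 annotations[[nms[k]]] else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Subgraph presence matrix for groups of structures
#'
#' Cell (row, id) is 1 when the row's structure (or any structure of the
#' row's group, with `aggregate = "group"`) contains the subgraph id among
#' its blocks and merged blocks; with `count = TRUE` cells count distinct
#' occurrences (vertex sets) instead. Columns are sorted by (V, n).
#'
#' @param structures named list of [complex_structure()] objects
#' @param groups character vector of group labels
#' @param catalog catalog (set) for matching
#' @param aggregate `"structure"` (one row each) or `"group"`
#' @param count presence (0/1) or occurrence counts
#' @param max_vertices passed to [merged_subgraphs()]
#' @return integer matrix with dimnames (rows, subgraph ids)
#' @export
subgraph_presence_matrix <- function(structures, groups, catalog = NULL,
                                     aggregate = c("structure", "group"),
                                     count = FALSE, max_vertices = 9L) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(structures) == length(groups))
  nms <- names(structures)
  if (is.null(nms)) nms <- vapply(structures, function(s) s$name, character(1L))
  per_structure <- lapply(structures, function(s) {
    g <- strip_self_loops(build_dual_graph(s))
    if (g$n_vertices < 2L) return(character(0))
    d <- block_decomposition(g, catalog = catalog)
    ms <- merged_subgraphs(d, max_vertices = max_vertices, catalog = catalog)
    ms$graph_id
  })
  row_labels <- if (aggregate == "structure") nms else unique(groups)
  ids <- sort_ids(unique(unlist(per_structure)))
  M <- matrix(0L, length(row_labels), max(1L, length(ids)),
              dimnames = list(row_labels,
                              if (length(ids)) ids else "none"))
  if (!length(ids)) return(M[, 0L, drop = FALSE])
  for (k in seq_along(structures)) {
    row <- if (aggregate == "structure") nms[k] else groups[k]
    tab <- table(per_structure[[k]])
    for (id in names(tab)) {
      add <- if (count) as.integer(tab[[id]]) else 1L
      M[row, id] <- if (count) M[row, id] + add else max(M[row, id], add)
    }
  }
  if (!count) M[M > 1L] <- 1L
  M
}

sort_ids <- function(ids) {
  if (!length(ids)) return(ids)
  V <- suppressWarnings(as.integer(sub("_.*", "", ids)))
  n <- suppressWarnings(id_index(ids))
  ids[order(is.na(V), V, n, ids)]
}

#' Least-squares log-linear fit of counts against vertex number
#'
#' Fits `log10(count) = a * n + b` by ordinary least squares, the linear form
#' of an exponential growth law `count = 10^b * (10^a)^n`.
#'
#' @param counts named numeric vector: names are vertex numbers, values are
#'   positive counts
#' @return list of class `loglinear_fit`: `slope`, `intercept`, `prefactor`
#'   (`10^intercept`), `base` (`10^slope`), and the underlying `lm` fit
#' @export
loglinear_fit <- function(counts) {
  n <- as.numeric(names(counts))
  y <- as.numeric(counts)
  if (length(y) < 3L) stop("log-linear fit requires at least 3 points")
  if (anyNA(n)) stop("counts must be named by vertex number")
  if (any(y <= 0)) stop("counts must be positive")
  fit <- stats::lm(log10(y) ~ n)
  a <- unname(stats::coef(fit)[2L])
  b <- unname(stats::coef(fit)[1L])
  structure(list(slope = a, intercept = b, prefactor = 10^b, base = 10^a,
                 fit = fit),
            class = "loglinear_fit")
}

#' @export
print.loglinear_fit <- function(x, ...) {
  cat(sprintf("log10(y) = %.4f n + %.4f   (y = %.3f * %.3f^n)\n",
              x$slope, x$intercept, x$prefactor, x$base))
  invisible(x)
}
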