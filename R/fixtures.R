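# Synthetic structure generation: realize catalog graphs as concrete
# dot-bracket structures (the inverse of build_dual_graph), and assemble
# multi-chain complex scenarios (polymers, chain breaks, DNA hybrids) for the
# substructure search. All randomness is seed-driven and reproducible.

#' Build a structure from a strand realization word
#'
#' Each word is an ordered sequence of vertex tokens over one strand; every
#' vertex appears exactly twice across all strands. Each token becomes a stem
#' block of `stem_len` base pairs; consecutive blocks are separated by
#' `loop_len` unpaired residues. The two blocks of a vertex pair up in
#' antiparallel orientation, so the dual graph of the result has exactly the
#' word's adjacency multiset as its edges (plus hairpin self-loops for
#' adjacent equal tokens).
#'
#' @param words list of integer vectors (one per strand), or a single vector
#' @param stem_len base pairs per stem (>= 2)
#' @param loop_len unpaired residues between consecutive blocks (>= 2, so
#'   that no accidental small-loop merging occurs)
#' @param molecule per-strand molecule types, recycled
#' @param chain_ids per-strand chain identifiers
#' @param name structure name
#' @param seed seed for the random sequence content
#' @return a [complex_structure()] with attribute `"word"`
#' @export
word_to_structure <- function(words, stem_len = 4L, loop_len = 4L,
                              molecule = "RNA", chain_ids = NULL,
                              name = "fixture", seed = 1L) {
  if (!is.list(words)) words <- list(words)
  stopifnot(stem_len >= 2L, loop_len >= 2L)
  all_tokens <- unlist(words)
  occ <- table(all_tokens)
  if (any(occ != 2L)) {
    integrity_error("each vertex must appear exactly twice across all strands")
  }
  molecule <- rep_len(molecule, length(words))
  if (is.null(chain_ids)) chain_ids <- make_chain_ids(length(words))
  set.seed(seed)
  residues <- NULL
  block_pos <- list()  # vertex -> list of position vectors
  pos0 <- 0L
  for (k in seq_along(words)) {
    w <- words[[k]]
    len <- length(w) * stem_len + max(0L, length(w) - 1L) * loop_len
    residues <- rbind(residues, data.frame(
      chain = chain_ids[k], molecule = molecule[k],
      serial = seq_len(len),
      base = if (molecule[k] == "DNA") sample(c("A", "C", "G", "T"), len, TRUE)
      else sample(c("A", "C", "G", "U"), len, TRUE),
      stringsAsFactors = FALSE))
    for (t in seq_along(w)) {
      start <- pos0 + (t - 1L) * (stem_len + loop_len) + 1L
      v <- as.character(w[t])
      block_pos[[v]] <- c(block_pos[[v]], list(start:(start + stem_len - 1L)))
    }
    pos0 <- pos0 + len
  }
  pairs <- do.call(rbind, lapply(block_pos, function(b) {
    cbind(b[[1L]], rev(b[[2L]]))
  }))
  s <- complex_structure(residues, pairs, name)
  attr(s, "word") <- words
  s
}

#' Realize a catalog graph as a concrete structure
#'
#' Searches for a single-strand realization word of the entry's edge multiset
#' (guaranteed to exist by the catalog membership rule): a noncrossing word
#' when the graph is unknotted, any word otherwise. The emitted structure's
#' dual graph matches the entry's id.
#'
#' @param e catalog entry (from [catalog_entry()]), multiplicity matrix, or
#'   `dual_graph`
#' @param stem_len,loop_len,seed passed to [word_to_structure()]
#' @return a [complex_structure()]; attributes `"word"` (audit trail)
#' @export
realize_graph <- function(e, stem_len = 4L, loop_len = 4L, seed = 1L) {
  adj <- if (is.list(e) && !is.null(e$adj)) e$adj
  else if (inherits(e, "dual_graph")) e$edge_mult
  else as.matrix(e)
  word <- find_realization_word(adj, noncrossing = TRUE)
  if (is.null(word)) word <- find_realization_word(adj, noncrossing = FALSE)
  if (is.null(word)) {
    integrity_error("graph has no single-strand realization (violates the catalog rule)")
  }
  nm <- if (is.list(e) && !is.null(e$entry)) paste0("realized_", e$entry$id)
  else "realized_graph"
  word_to_structure(word, stem_len = stem_len, loop_len = loop_len,
                    name = nm, seed = seed)
}

#' Random single-chain structure for fuzz tests
#'
#' Generates a double-occurrence word on `n_stems` stems: a uniformly random
#' stack-discipline (noncrossing) word when `pk_probability` is 0; otherwise,
#' with the given probability, a uniformly random double-occurrence word
#' (usually crossing). The word is realized via [word_to_structure()].
#'
#' @param n_stems number of stems (<= 9)
#' @param pk_probability probability of drawing an unconstrained
#'   (possibly pseudoknotted) word
#' @param seed integer seed fixing all randomness
#' @param stem_len,loop_len stem/loop geometry
#' @return a [complex_structure()] with attribute `"word"`
#' @export
random_structure <- function(n_stems, pk_probability = 0, seed = 1L,
                             stem_len = 4L, loop_len = 4L) {
  stopifnot(n_stems >= 1L, n_stems <= 9L)
  set.seed(seed)
  crossing <- stats::runif(1L) < pk_probability
  word <- if (crossing) {
    sample(rep(seq_len(n_stems), 2L))
  } else {
    # random stack-discipline word
    counts <- integer(n_stems)
    stack <- integer(0)
    w <- integer(0)
    unopened <- seq_len(n_stems)
    while (length(w) < 2L * n_stems) {
      can_open <- length(unopened) > 0L
      can_close <- length(stack) > 0L
      open <- if (can_open && can_close) stats::runif(1L) < 0.5 else can_open
      if (open) {
        v <- if (length(unopened) == 1L) unopened else sample(unopened, 1L)
        unopened <- setdiff(unopened, v)
        stack <- c(stack, v)
        w <- c(w, v)
      } else {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        w <- c(w, v)
      }
    }
    w
  }
  word_to_structure(word, stem_len = stem_len, loop_len = loop_len,
                    name = sprintf("random_%d", seed), seed = seed + 1L)
}

# ---------------------------------------------------------------------------
# Multi-chain complex scenarios.

#' Specification for a synthetic multi-chain complex
#'
#' @param chains list of `list(id=, len=, molecule=)` entries
#' @param helices list of `list(a=, b=, bp=)` entries: `bp` base pairs between
#'   chains `a` and `b` (equal ids give a hairpin stem within the chain).
#'   Successive helices consume residues from each chain front to back, with a
#'   3-nt spacer, so all pairings are consistent by construction.
#' @param duplications list of `list(source=, id=, mutations=)`: append a copy
#'   of chain `source` named `id` with `mutations` random point changes, fully
#'   base-paired to the source (a crystallographic polymer mimic).
#' @param breaks list of `list(chain=, after=)`: add a serial jump in `chain`
#'   after its `after`-th residue, splitting it into subchains.
#' @param seed integer seed
#' @return list of class `scenario_spec`
#' @export
scenario_spec <- function(chains, helices = list(), duplications = list(),
                          breaks = list(), seed = 1L) {
  structure(list(chains = chains, helices = helices,
                 duplications = duplications, breaks = breaks, seed = seed),
            class = "scenario_spec")
}

#' Build a complex-table text from a scenario specification
#'
#' Deterministic for a fixed seed. Duplication directives produce
#' near-identical subchains for polymer-filter tests; break directives split
#' serial numbering.
#'
#' @param spec a [scenario_spec()]
#' @return complex-table TSV text (parseable by [parse_structure()])
#' @export
make_complex_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  chains <- list()
  for (ch in spec$chains) {
    alph <- if (identical(ch$molecule, "DNA")) c("A", "C", "G", "T")
    else c("A", "C", "G", "U")
    chains[[ch$id]] <- list(id = ch$id,
                            molecule = ch$molecule %||% "RNA",
                            base = sample(alph, ch$len, TRUE),
                            cursor = 1L)
  }
  pairs <- list()  # list of (chain_a, idx_a, chain_b, idx_b)
  take <- function(id, n) {
    ch <- chains[[id]]
    if (ch$cursor + n - 1L > length(ch$base)) {
      stop(sprintf("chain %s too short for requested helices", id))
    }
    idx <- ch$cursor:(ch$cursor + n - 1L)
    chains[[id]]$cursor <<- ch$cursor + n + 3L  # 3-nt spacer
    idx
  }
  intra <- list()  # per chain: list of (ia, ib) index pairs of its hairpin stems
  for (h in spec$helices) {
    if (identical(h$a, h$b)) {
      ia <- take(h$a, h$bp)
      ib <- take(h$a, h$bp)
      pairs[[length(pairs) + 1L]] <- cbind(h$a, ia, h$a, rev(ib))
      intra[[h$a]] <- c(intra[[h$a]], list(list(ia = ia, ib = ib)))
    } else {
      ia <- take(h$a, h$bp)
      ib <- take(h$b, h$bp)
      pairs[[length(pairs) + 1L]] <- cbind(h$a, ia, h$b, rev(ib))
    }
  }
  for (dup in spec$duplications) {
    src <- chains[[dup$source]]
    base <- src$base
    nmut <- dup$mutations %||% 0L
    if (nmut > 0L) {
      at <- sample(seq_along(base), min(nmut, length(base)))
      alph <- if (identical(src$molecule, "DNA")) c("A", "C", "G", "T")
      else c("A", "C", "G", "U")
      for (i in at) base[i] <- sample(setdiff(alph, base[i]), 1L)
    }
    chains[[dup$id]] <- list(id = dup$id, molecule = src$molecule,
                             base = base, cursor = src$cursor)
    # replicate the source's intra-chain stems, so the copies share both
    # sequence and 2D structure (a crystallographic polymer mimic) ...
    for (st in intra[[dup$source]]) {
      pairs[[length(pairs) + 1L]] <- cbind(dup$id, st$ia, dup$id, rev(st$ib))
    }
    # ... and add a short inter-copy contact above the grouping threshold
    link <- dup$link_bp %||% 2L
    ia <- take(dup$source, link)
    ib <- take(dup$id, link)
    pairs[[length(pairs) + 1L]] <- cbind(dup$source, ia, dup$id, rev(ib))
  }
  # residue table with serial jumps at breaks
  rows <- list()
  for (ch in chains) {
    pos <- seq_along(ch$base)
    serial <- pos
    for (b in spec$breaks) {
      if (identical(b$chain, ch$id)) serial[pos > b$after] <- serial[pos > b$after] + 10L
    }
    rows[[ch$id]] <- data.frame(chain = ch$id, molecule = ch$molecule,
                                serial = serial, base = ch$base,
                                pair_chain = "", pair_serial = "",
                                stringsAsFactors = FALSE)
  }
  for (p in pairs) {
    for (r in seq_len(nrow(p))) {
      a <- p[r, 1L]; ia <- as.integer(p[r, 2L])
      b <- p[r, 3L]; ib <- as.integer(p[r, 4L])
      rows[[a]]$pair_chain[ia] <- b
      rows[[a]]$pair_serial[ia] <- as.character(rows[[b]]$serial[ib])
      rows[[b]]$pair_chain[ib] <- a
      rows[[b]]$pair_serial[ib] <- as.character(rows[[a]]$serial[ia])
    }
  }
  df <- do.call(rbind, rows)
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random multi-chain scenario for property tests
#'
#' Draws 2..6 RNA chains and a random set of inter- and intra-chain helices
#' (1..4 base pairs each), occasionally a polymer duplication or a chain
#' break, and returns the parsed structure.
#'
#' @param seed integer seed
#' @return a [complex_structure()]
#' @export
random_scenario <- function(seed) {
  set.seed(seed)
  n_chains <- sample(2:6, 1L)
  ids <- LETTERS[seq_len(n_chains)]
  chains <- lapply(ids, function(id) list(id = id, len = 60L, molecule = "RNA"))
  n_hel <- sample(1:6, 1L)
  helices <- lapply(seq_len(n_hel), function(k) {
    ab <- sample(ids, 2L, replace = TRUE)
    list(a = ab[1L], b = ab[2L], bp = sample(1:4, 1L))
  })
  breaks <- if (stats::runif(1L) < 0.3) {
    list(list(chain = sample(ids, 1L), after = sample(10:50, 1L)))
  } else list()
  dups <- if (stats::runif(1L) < 0.2) {
    list(list(source = ids[1L], id = "Z", mutations = 1L))
  } else list()
  spec <- scenario_spec(chains, helices, duplications = dups, breaks = breaks,
                        seed = seed + 1000L)
  parse_structure(make_complex_scenario(spec), format = "complex_tsv")
}
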