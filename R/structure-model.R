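# Data model for multi-chain nucleic-acid secondary structures.
#
# A complex_structure holds a residue table (one row per nucleotide, in file
# order), a derived subchain table (maximal continuous runs within a chain),
# and a base-pair matching expressed in global residue positions.

VALID_BASES <- c("A", "C", "G", "U", "T", "N")

#' Error helpers
#'
#' Parsing problems raise condition class `rnadual_parse_error`; inconsistent
#' pairing information raises `rnadual_integrity_error`. Both inherit from
#' `rnadual_error` so callers can catch either.
#' @noRd
parse_error <- function(msg) {
  stop(structure(class = c("rnadual_parse_error", "rnadual_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

integrity_error <- function(msg) {
  stop(structure(class = c("rnadual_integrity_error", "rnadual_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Split a residue table into continuous subchains
#'
#' A new subchain starts at every chain change, at every serial gap (serial
#' increment different from 1), and wherever the `break_before` flag is set
#' (used by explicit BREAK markers in the complex table format). Subchains are
#' numbered 1.. within each chain, giving identifiers like `"B-1"`, `"B-2"`.
#'
#' @param residues data.frame with columns `chain`, `serial`, and optionally
#'   `break_before` (logical). Rows must be grouped by chain and ordered by
#'   serial within each chain.
#' @return the residue table with added columns `subchain` (identifier) and
#'   `sub_index` (1-based index within the chain), plus an attribute
#'   `"subchains"` summarising each subchain.
#' @export
split_subchains <- function(residues) {
  stopifnot(is.data.frame(residues), all(c("chain", "serial") %in% names(residues)))
  n <- nrow(residues)
  if (n == 0L) parse_error("structure contains no residues")
  key <- paste(residues$chain, residues$serial)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    integrity_error(sprintf("duplicate residue (chain, serial): %s", dup))
  }
  brk <- if ("break_before" %in% names(residues)) residues$break_before else rep(FALSE, n)
  brk[is.na(brk)] <- FALSE
  new_chain <- c(TRUE, residues$chain[-1L] != residues$chain[-n])
  gap <- c(TRUE, diff(residues$serial) != 1L)
  starts <- new_chain | gap | brk
  seg <- cumsum(starts)
  # per-chain 1-based numbering of segments
  sub_index <- integer(n)
  for (ch in unique(residues$chain)) {
    sel <- residues$chain == ch
    sub_index[sel] <- match(seg[sel], unique(seg[sel]))
  }
  residues$sub_index <- sub_index
  residues$subchain <- paste0(residues$chain, "-", sub_index)
  first <- which(starts)
  last <- c(first[-1L] - 1L, n)
  attr(residues, "subchains") <- data.frame(
    id = residues$subchain[first],
    chain = residues$chain[first],
    index = residues$sub_index[first],
    start = first, end = last,
    length = last - first + 1L,
    molecule = if ("molecule" %in% names(residues)) residues$molecule[first] else "RNA",
    stringsAsFactors = FALSE
  )
  residues
}

#' Construct a complex structure from a residue table and pair list
#'
#' @param residues data.frame with columns `chain`, `serial`, `base`,
#'   `molecule` (and optionally `break_before`), in 5'-to-3' file order.
#' @param pairs two-column integer matrix of global residue positions
#'   (row indices into `residues`); unordered, one row per base pair.
#' @param name structure name.
#' @return object of class `complex_structure` with elements `name`,
#'   `residues`, `subchains`, `pairs` (matrix with columns i < j, sorted by i).
#' @export
complex_structure <- function(residues, pairs, name = "structure") {
  if (!"molecule" %in% names(residues)) residues$molecule <- "RNA"
  if (!"base" %in% names(residues)) residues$base <- "N"
  residues$base <- toupper(residues$base)
  bad <- !residues$base %in% VALID_BASES
  if (any(bad)) {
    integrity_error(sprintf("invalid base '%s' at position %d",
                            residues$base[which(bad)[1L]], which(bad)[1L]))
  }
  if (!all(residues$molecule %in% c("RNA", "DNA"))) {
    integrity_error("molecule must be 'RNA' or 'DNA'")
  }
  residues <- split_subchains(residues)
  subchains <- attr(residues, "subchains")
  attr(residues, "subchains") <- NULL
  n <- nrow(residues)
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  }
  storage.mode(pairs) <- "integer"
  if (ncol(pairs) != 2L) parse_error("pairs must have two columns")
  if (nrow(pairs) > 0L) {
    if (any(pairs < 1L | pairs > n)) integrity_error("pair endpoint outside structure")
    if (any(pairs[, 1L] == pairs[, 2L])) {
      integrity_error(sprintf("residue paired to itself at position %d",
                              pairs[which(pairs[, 1L] == pairs[, 2L])[1L], 1L]))
    }
    pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
    pairs <- pairs[!duplicated(pairs), , drop = FALSE]
    cnt <- tabulate(pairs, nbins = n)
    if (any(cnt > 1L)) {
      integrity_error(sprintf("residue at position %d participates in more than one pair",
                              which(cnt > 1L)[1L]))
    }
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  rownames(residues) <- NULL
  structure(list(name = name, residues = residues, subchains = subchains,
                 pairs = pairs),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("<complex_structure '%s': %d residues, %d subchains, %d pairs>\n",
              x$name, nrow(x$residues), nrow(x$subchains), nrow(x$pairs)))
  invisible(x)
}

#' Number of residues
#' @param s a `complex_structure`
#' @export
n_residues <- function(s) nrow(s$residues)

#' Partner vector: for each global position, its paired position (0 if unpaired)
#' @noRd
partner_vector <- function(s) {
  p <- integer(nrow(s$residues))
  if (nrow(s$pairs)) {
    p[s$pairs[, 1L]] <- s$pairs[, 2L]
    p[s$pairs[, 2L]] <- s$pairs[, 1L]
  }
  p
}

#' Extract one subchain with its sequence and pairing string
#'
#' The pairing string is over `{'.', 'p'}`: `'p'` where the residue is paired
#' (to any partner, inside or outside the subchain), `'.'` otherwise.
#'
#' @param s a `complex_structure`
#' @param id subchain identifier such as `"B-2"`
#' @return list with `id`, `chain`, `molecule`, `sequence`, `pairing`,
#'   `start`, `end` (global positions)
#' @export
get_subchain <- function(s, id) {
  row <- match(id, s$subchains$id)
  if (is.na(row)) parse_error(sprintf("no subchain '%s'", id))
  sc <- s$subchains[row, ]
  idx <- sc$start:sc$end
  paired <- partner_vector(s)[idx] > 0L
  list(id = sc$id, chain = sc$chain, molecule = sc$molecule,
       sequence = paste(s$residues$base[idx], collapse = ""),
       pairing = paste(ifelse(paired, "p", "."), collapse = ""),
       start = sc$start, end = sc$end)
}

# ---------------------------------------------------------------------------
# Dot-bracket bracket layers: "()" "[]" "{}" "<>" then "Aa" .. "Zz".
LAYER_OPEN  <- c("(", "[", "{", "<", LETTERS)
LAYER_CLOSE <- c(")", "]", "}", ">", letters)

#' Parse a secondary structure file or literal text
#'
#' Supported formats:
#' \describe{
#'   \item{dotbracket}{optional `>name` header, optional sequence line, one
#'     structure line. Bracket layers are drawn from `()[]{}<>` then `Aa`..`Zz`
#'     (uppercase opens, lowercase closes); `&` separates strands, which become
#'     chains A, B, ...}
#'   \item{ct}{six-column connectivity table; a 0 in the "previous" column
#'     marks a strand break.}
#'   \item{bpseq}{three columns `index base partner` (0 = unpaired).}
#'   \item{complex_tsv}{tab-separated with header
#'     `chain molecule serial base pair_chain pair_serial`; `pair_chain` /
#'     `pair_serial` empty when unpaired. A row whose `base` field is `BREAK`
#'     forces a subchain split before the next residue of that chain.}
#' }
#'
#' @param path_or_text path to a file, or the file content itself (anything
#'   that is not an existing file path is treated as text).
#' @param format one of `"auto"`, `"dotbracket"`, `"ct"`, `"bpseq"`,
#'   `"complex_tsv"`.
#' @param keep_first_pair if `TRUE`, non-reciprocal partner claims (a residue
#'   named as partner by several others) are pruned deterministically, each
#'   residue keeping its lowest-position partner; the default is to raise an
#'   integrity error.
#' @return a [complex_structure()]
#' @export
parse_structure <- function(path_or_text, format = c("auto", "dotbracket", "ct",
                                                     "bpseq", "complex_tsv"),
                            keep_first_pair = FALSE) {
  format <- match.arg(format)
  is_file <- length(path_or_text) == 1L && !grepl("\n", path_or_text) &&
    file.exists(path_or_text)
  if (is_file) {
    text <- paste(readLines(path_or_text, warn = FALSE), collapse = "\n")
    name <- sub("\\.[^.]*$", "", basename(path_or_text))
    if (format == "auto") {
      ext <- tolower(tools::file_ext(path_or_text))
      format <- switch(ext, ct = "ct", bpseq = "bpseq",
                       tsv = "complex_tsv", dbn = "dotbracket", db = "dotbracket",
                       "auto")
    }
  } else {
    text <- paste(path_or_text, collapse = "\n")
    name <- "structure"
  }
  if (format == "auto") format <- sniff_format(text)
  switch(format,
         dotbracket = parse_dotbracket(text, name),
         ct = parse_ct(text, name, keep_first_pair),
         bpseq = parse_bpseq(text, name, keep_first_pair),
         complex_tsv = parse_complex_tsv(text, name))
}

sniff_format <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) parse_error("empty input")
  if (any(grepl("^chain\t", lines))) return("complex_tsv")
  if (any(grepl("[().<>{}]|\\[|\\]", lines) & !grepl("\t", lines))) return("dotbracket")
  first_data <- lines[!grepl("^[>#]", lines)][1L]
  nf <- length(strsplit(trimws(first_data), "[ \t]+")[[1L]])
  if (nf >= 6L) return("ct")
  if (nf == 3L) return("bpseq")
  parse_error("could not determine input format")
}

#' Match one bracket layer over a linear structure string
#' @noRd
match_layer <- function(chars, open, close) {
  stack <- integer(0)
  out <- list()
  for (k in seq_along(chars)) {
    if (chars[k] == open) {
      stack <- c(stack, k)
    } else if (chars[k] == close) {
      if (!length(stack)) {
        parse_error(sprintf("unbalanced bracket '%s' at position %d", close, k))
      }
      out[[length(out) + 1L]] <- c(stack[length(stack)], k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) {
    parse_error(sprintf("unbalanced bracket '%s' at position %d", open, stack[length(stack)]))
  }
  out
}

parse_dotbracket <- function(text, name = "structure") {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1L], ">")) {
    name <- trimws(sub("^>", "", lines[1L]))
    lines <- lines[-1L]
  }
  if (!length(lines)) parse_error("dot-bracket record has no structure line")
  # standard layout: optional sequence line, then the structure line
  # (sequence letters collide with letter bracket layers, so layout decides)
  if (length(lines) >= 2L) {
    seq_line <- lines[1L]
    struct_line <- lines[2L]
  } else {
    seq_line <- NULL
    struct_line <- lines[1L]
  }
  strands <- strsplit(struct_line, "&", fixed = TRUE)[[1L]]
  if (!is.null(seq_line)) {
    seq_strands <- strsplit(toupper(seq_line), "&", fixed = TRUE)[[1L]]
    if (length(seq_strands) != length(strands) ||
        any(nchar(seq_strands) != nchar(strands))) {
      parse_error("sequence and structure lines disagree in length or strand count")
    }
  } else {
    seq_strands <- vapply(strands, function(x) strrep("N", nchar(x)), character(1L))
  }
  chains <- make_chain_ids(length(strands))
  residues <- do.call(rbind, lapply(seq_along(strands), function(k) {
    data.frame(chain = chains[k], molecule = "RNA",
               serial = seq_len(nchar(strands[k])),
               base = strsplit(seq_strands[k], "")[[1L]],
               stringsAsFactors = FALSE)
  }))
  chars <- strsplit(paste(strands, collapse = ""), "")[[1L]]
  bad <- !chars %in% c(LAYER_OPEN, LAYER_CLOSE, ".", "-")
  if (any(bad)) parse_error(sprintf("invalid structure character '%s' at position %d",
                                    chars[which(bad)[1L]], which(bad)[1L]))
  pairs <- list()
  for (layer in seq_along(LAYER_OPEN)) {
    if (any(chars %in% c(LAYER_OPEN[layer], LAYER_CLOSE[layer]))) {
      pairs <- c(pairs, match_layer(chars, LAYER_OPEN[layer], LAYER_CLOSE[layer]))
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else matrix(integer(0), ncol = 2L)
  complex_structure(residues, pairs, name)
}

make_chain_ids <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)] else paste0("C", seq_len(n))
}

#' Resolve directed partner claims into a matching
#' @noRd
claims_to_pairs <- function(claim, keep_first_pair) {
  # claim: integer vector, claim[i] = partner position of i (0 = unpaired)
  n <- length(claim)
  idx <- which(claim > 0L)
  if (any(claim[idx] == idx)) {
    integrity_error(sprintf("residue at position %d paired to itself",
                            idx[which(claim[idx] == idx)[1L]]))
  }
  if (any(claim > n)) integrity_error("pair partner outside structure")
  recip <- idx[claim[claim[idx]] == idx]
  if (length(recip) < length(idx)) {
    bad <- setdiff(idx, recip)
    if (!keep_first_pair) {
      i <- bad[1L]
      integrity_error(sprintf(
        "inconsistent pairing: position %d pairs %d but %d pairs %d",
        i, claim[i], claim[i], claim[claim[i]]))
    }
    # deterministic pruning: a residue claimed by several keeps the lowest claimant
    claimed_by <- split(idx, claim[idx])
    keep <- rep(FALSE, n)
    for (tgt in names(claimed_by)) {
      keep[min(claimed_by[[tgt]])] <- TRUE
    }
    idx <- idx[keep[idx]]
    recip <- idx[claim[idx] %in% idx & claim[claim[idx]] == idx]
  }
  m <- cbind(recip, claim[recip])
  m <- m[m[, 1L] < m[, 2L], , drop = FALSE]
  m
}

parse_ct <- function(text, name, keep_first_pair = FALSE) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  nres <- suppressWarnings(as.integer(header[1L]))
  if (is.na(nres)) parse_error("CT header must start with the residue count")
  if (length(header) > 1L) name <- paste(header[-1L], collapse = " ")
  body <- lines[-1L]
  if (length(body) < nres) parse_error("CT file shorter than header count")
  fields <- strsplit(trimws(body[seq_len(nres)]), "[ \t]+")
  mat <- t(vapply(fields, function(f) f[1:6], character(6L)))
  idx <- as.integer(mat[, 1L])
  if (any(idx != seq_len(nres))) parse_error("CT indices must be 1..N in order")
  prev <- as.integer(mat[, 3L])
  residues <- data.frame(chain = "A", molecule = "RNA",
                         serial = as.integer(mat[, 6L]),
                         base = toupper(mat[, 2L]),
                         break_before = c(FALSE, prev[-1L] == 0L),
                         stringsAsFactors = FALSE)
  pairs <- claims_to_pairs(as.integer(mat[, 5L]), keep_first_pair)
  complex_structure(residues, pairs, name)
}

parse_bpseq <- function(text, name, keep_first_pair = FALSE) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  fields <- strsplit(lines, "[ \t]+")
  mat <- t(vapply(fields, function(f) f[1:3], character(3L)))
  idx <- as.integer(mat[, 1L])
  if (any(idx != seq_along(idx))) parse_error("BPSEQ indices must be 1..N in order")
  residues <- data.frame(chain = "A", molecule = "RNA", serial = idx,
                         base = toupper(mat[, 2L]), stringsAsFactors = FALSE)
  pairs <- claims_to_pairs(as.integer(mat[, 3L]), keep_first_pair)
  complex_structure(residues, pairs, name)
}

parse_complex_tsv <- function(text, name = "structure") {
  df <- utils::read.delim(text = text, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("chain", "molecule", "serial", "base", "pair_chain", "pair_serial")
  if (!all(need %in% names(df))) {
    parse_error(sprintf("complex table must have columns: %s",
                        paste(need, collapse = ", ")))
  }
  is_break <- toupper(df$base) == "BREAK"
  # BREAK rows flag the next residue of the same chain
  break_before <- rep(FALSE, nrow(df))
  for (r in which(is_break)) {
    later <- which(!is_break & df$chain == df$chain[r])
    later <- later[later > r]
    if (length(later)) break_before[later[1L]] <- TRUE
  }
  keep <- !is_break
  df <- df[keep, , drop = FALSE]
  break_before <- break_before[keep]
  residues <- data.frame(chain = df$chain,
                         molecule = toupper(df$molecule),
                         serial = as.integer(df$serial),
                         base = toupper(df$base),
                         break_before = break_before,
                         stringsAsFactors = FALSE)
  key <- paste(residues$chain, residues$serial)
  pos <- seq_len(nrow(df))
  claim <- integer(nrow(df))
  has_pair <- nzchar(trimws(df$pair_chain)) & nzchar(trimws(df$pair_serial))
  claim[has_pair] <- match(paste(df$pair_chain[has_pair],
                                 as.integer(df$pair_serial[has_pair])), key)
  if (anyNA(claim)) {
    bad <- which(is.na(claim))[1L]
    integrity_error(sprintf("pair partner %s %s of row %d not found in table",
                            df$pair_chain[bad], df$pair_serial[bad], bad))
  }
  pairs <- claims_to_pairs(claim, keep_first_pair = FALSE)
  complex_structure(residues, pairs, name)
}

# ---------------------------------------------------------------------------

#' Write a structure as layered dot-bracket text
#'
#' Crossing pairs are assigned to distinct bracket layers by greedy first-fit
#' over the fixed layer order `()[]{}<>` then `Aa`..`Zz`. Strands (subchain
#' boundaries) are separated by `&`. Round-trips through [parse_structure()]
#' with identical pairs and subchain boundaries.
#'
#' @param s a [complex_structure()]
#' @return a single string: `>name`, sequence line, structure line
#' @export
write_dotbracket <- function(s) {
  n <- nrow(s$residues)
  chars <- rep(".", n)
  P <- s$pairs
  if (nrow(P)) {
    ord <- order(P[, 1L])
    P <- P[ord, , drop = FALSE]
    layer_of <- integer(nrow(P))
    # pairs already held per layer, as a list of matrices
    layers <- list()
    for (r in seq_len(nrow(P))) {
      i <- P[r, 1L]; j <- P[r, 2L]
      placed <- FALSE
      for (L in seq_along(layers)) {
        prev <- layers[[L]]
        crosses <- any((prev[, 1L] < i & i < prev[, 2L] & prev[, 2L] < j) |
                         (i < prev[, 1L] & prev[, 1L] < j & j < prev[, 2L]))
        if (!crosses) {
          layers[[L]] <- rbind(prev, c(i, j)); layer_of[r] <- L; placed <- TRUE
          break
        }
      }
      if (!placed) {
        if (length(layers) >= length(LAYER_OPEN)) {
          parse_error("structure needs more crossing layers than available bracket symbols")
        }
        layers[[length(layers) + 1L]] <- matrix(c(i, j), ncol = 2L)
        layer_of[r] <- length(layers)
      }
    }
    chars[P[, 1L]] <- LAYER_OPEN[layer_of]
    chars[P[, 2L]] <- LAYER_CLOSE[layer_of]
  }
  seqs <- character(nrow(s$subchains))
  structs <- character(nrow(s$subchains))
  for (k in seq_len(nrow(s$subchains))) {
    idx <- s$subchains$start[k]:s$subchains$end[k]
    seqs[k] <- paste(s$residues$base[idx], collapse = "")
    structs[k] <- paste(chars[idx], collapse = "")
  }
  paste0(">", s$name, "\n", paste(seqs, collapse = "&"), "\n",
         paste(structs, collapse = "&"), "\n")
}

#' Write a structure as a complex table (TSV)
#'
#' Explicit `BREAK` rows are emitted where a subchain boundary is not implied
#' by a serial gap or chain change.
#' @param s a [complex_structure()]
#' @return TSV text with header `chain molecule serial base pair_chain pair_serial`
#' @export
write_complex_tsv <- function(s) {
  res <- s$residues
  p <- partner_vector(s)
  pair_chain <- ifelse(p > 0L, res$chain[pmax(p, 1L)], "")
  pair_serial <- ifelse(p > 0L, as.character(res$serial[pmax(p, 1L)]), "")
  lines <- c("chain\tmolecule\tserial\tbase\tpair_chain\tpair_serial")
  n <- nrow(res)
  implied <- c(TRUE, res$chain[-1L] != res$chain[-n] | diff(res$serial) != 1L)
  boundary <- c(TRUE, res$subchain[-1L] != res$subchain[-n])
  for (r in seq_len(n)) {
    if (r > 1L && boundary[r] && !implied[r]) {
      lines <- c(lines, paste(res$chain[r], res$molecule[r], "", "BREAK", "", "",
                              sep = "\t"))
    }
    lines <- c(lines, paste(res$chain[r], res$molecule[r], res$serial[r],
                            res$base[r], pair_chain[r], pair_serial[r], sep = "\t"))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Does the structure contain crossing (pseudoknotted) base pairs?
#'
#' Two pairs (i,j) and (k,l) cross when i < k < j < l in the linear coordinate
#' induced by concatenating subchains in `concat_order`.
#'
#' @param s a [complex_structure()]
#' @param concat_order character vector of subchain ids covering all subchains
#'   exactly once; defaults to the file order.
#' @return `TRUE` if any two pairs interleave
#' @export
has_crossing <- function(s, concat_order = NULL) {
  if (is.null(concat_order)) concat_order <- s$subchains$id
  if (!setequal(concat_order, s$subchains$id) ||
      length(concat_order) != nrow(s$subchains)) {
    parse_error("concat_order must cover all subchains exactly once")
  }
  rows <- match(concat_order, s$subchains$id)
  lin <- integer(nrow(s$residues))
  off <- 0L
  for (r in rows) {
    idx <- s$subchains$start[r]:s$subchains$end[r]
    lin[idx] <- off + seq_along(idx)
    off <- off + length(idx)
  }
  P <- s$pairs
  if (nrow(P) < 2L) return(FALSE)
  a <- pmin(lin[P[, 1L]], lin[P[, 2L]])
  b <- pmax(lin[P[, 1L]], lin[P[, 2L]])
  for (r in seq_len(nrow(P) - 1L)) {
    k <- (r + 1L):nrow(P)
    if (any((a[r] < a[k] & a[k] < b[r] & b[r] < b[k]) |
            (a[k] < a[r] & a[r] < b[k] & b[k] < b[r]))) return(TRUE)
  }
  FALSE
}

# ---------------------------------------------------------------------------

#' Sequence and 2D-structure identity between two subchains
#'
#' Global (Needleman-Wunsch) alignment maximising the number of sequence
#' matches (match +1, mismatch and gap 0). `seq_identity` is matches divided
#' by alignment length; `struct_identity` is the fraction of alignment columns
#' whose pairing states agree (a gap column never agrees). Ties in the
#' traceback prefer diagonal, then the first sequence's gap; arguments are
#' ordered canonically first, so the result is symmetric.
#'
#' @param a,b subchain objects from [get_subchain()] (lists with `sequence`
#'   and `pairing`)
#' @return named numeric vector `c(seq_identity=, struct_identity=)`
#' @export
chain_similarity <- function(a, b) {
  key_a <- paste(a$sequence, a$pairing)
  key_b <- paste(b$sequence, b$pairing)
  if (key_b < key_a) { tmp <- a; a <- b; b <- tmp }
  x <- strsplit(a$sequence, "")[[1L]]
  y <- strsplit(b$sequence, "")[[1L]]
  px <- strsplit(a$pairing, "")[[1L]]
  py <- strsplit(b$pairing, "")[[1L]]
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) parse_error("subchains must be nonempty")
  S <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + (x[i] == y[j]),
                               S[i, j + 1L], S[i + 1L, j])
    }
  }
  # traceback, preferring diagonal then up (gap in y) then left
  i <- n; j <- m
  cols_x <- integer(0); cols_y <- integer(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L && S[i + 1L, j + 1L] == S[i, j] + (x[i] == y[j])) {
      cols_x <- c(i, cols_x); cols_y <- c(j, cols_y); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L]) {
      cols_x <- c(i, cols_x); cols_y <- c(0L, cols_y); i <- i - 1L
    } else {
      cols_x <- c(0L, cols_x); cols_y <- c(j, cols_y); j <- j - 1L
    }
  }
  len <- length(cols_x)
  both <- cols_x > 0L & cols_y > 0L
  seq_id <- sum(both & x[pmax(cols_x, 1L)] == y[pmax(cols_y, 1L)]) / len
  struct_id <- sum(both & px[pmax(cols_x, 1L)] == py[pmax(cols_y, 1L)]) / len
  c(seq_identity = seq_id, struct_identity = struct_id)
}

#' Restrict a structure to a set of subchains
#'
#' Keeps the named subchains (in original order) and every base pair whose two
#' endpoints both survive.
#' @param s a [complex_structure()]
#' @param subchain_ids subchain identifiers to keep
#' @param name name for the restricted structure
#' @return a [complex_structure()]
#' @export
restrict_structure <- function(s, subchain_ids, name = s$name) {
  rows <- which(s$subchains$id %in% subchain_ids)
  if (!length(rows)) parse_error("no matching subchains to restrict to")
  keep <- unlist(lapply(rows, function(r) s$subchains$start[r]:s$subchains$end[r]))
  newpos <- integer(nrow(s$residues))
  newpos[keep] <- seq_along(keep)
  P <- s$pairs
  P <- P[P[, 1L] %in% keep & P[, 2L] %in% keep, , drop = FALSE]
  P <- cbind(newpos[P[, 1L]], newpos[P[, 2L]])
  res <- s$residues[keep, c("chain", "molecule", "serial", "base"), drop = FALSE]
  # preserve explicit breaks that are not serial gaps
  sub_id <- s$residues$subchain[keep]
  res$break_before <- c(FALSE, sub_id[-1L] != sub_id[-length(sub_id)])
  complex_structure(res, P, name)
}
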