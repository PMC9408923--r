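test_that("catalog enumeration is exhaustive for small vertex counts", {
  expect_equal(nrow(enumerate_catalog(1L)$entries), 1L)
  expect_equal(nrow(enumerate_catalog(2L)$entries), 3L)
  c3 <- enumerate_catalog(3L)
  expect_equal(nrow(c3$entries), 8L)
  # hand enumeration: 4 paths {1,1},{1,2},{1,3},{2,2}; 4 triangles
  # {1,1,1},{1,1,2},{1,1,3},{1,2,2}
  n_edges <- vapply(c3$adj, function(a) sum(a > 0L) / 2L, numeric(1L))
  expect_equal(sort(table(n_edges)), sort(c(`2` = 4L, `3` = 4L)),
               ignore_attr = TRUE)
  expect_equal(nrow(enumerate_catalog(4L)$entries), 29L)
  expect_error(enumerate_catalog(0L))
  expect_error(enumerate_catalog(10L))
})

test_that("V=2 ids order multiplicity 1, 2, 3 by Fiedler values 2, 4, 6", {
  c2 <- enumerate_catalog(2L)
  expect_equal(c2$entries$fiedler, c(2, 4, 6))
  expect_equal(vapply(c2$adj, function(a) a[1L, 2L], integer(1L)), 1:3)
})

test_that("V=3 id assignment reproduces the published anchors", {
  c3 <- enumerate_catalog(3L)
  # path {2,2} (internal-loop chain) ranks 4th
  expect_equal(match_graph(mk_adj(3L, list(c(1, 2, 2), c(2, 3, 2))), c3), "3_4")
  # unit triangle (three-way junction) ranks 5th
  expect_equal(match_graph(mk_adj(3L, list(c(1, 2, 1), c(2, 3, 1), c(3, 1, 1))), c3),
               "3_5")
  # flanked H-type pseudoknot: triangle {1,1,3}
  expect_equal(match_graph(mk_adj(3L, list(c(1, 2, 1), c(2, 3, 1), c(3, 1, 3))), c3),
               "3_7")
  # triple-edge plus unit-edge path ranks 3rd
  expect_equal(match_graph(mk_adj(3L, list(c(1, 2, 3), c(2, 3, 1))), c3), "3_3")
  # Fiedler values are non-decreasing in n
  expect_true(all(diff(c3$entries$fiedler) >= 0))
})

test_that("Laplacian spectrum keys match closed forms", {
  expect_equal(laplacian_spectrum_key(mk_adj(2L, list(c(1, 2, 1)))), c(0, 2))
  expect_equal(laplacian_spectrum_key(mk_adj(2L, list(c(1, 2, 3)))), c(0, 6))
  expect_equal(laplacian_spectrum_key(mk_adj(3L, list(c(1, 2, 1), c(2, 3, 1),
                                                      c(3, 1, 1)))), c(0, 3, 3))
  disconnected <- matrix(0L, 2L, 2L)
  expect_error(laplacian_spectrum_key(disconnected),
               class = "rnadual_integrity_error")
})

test_that("certificates agree with brute-force isomorphism on all V<=4 pairs", {
  mats <- c(enumerate_catalog(3L)$adj, enumerate_catalog(4L)$adj)
  certs <- vapply(mats, canonical_certificate, character(1L))
  # relabeling invariance
  tri <- mk_adj(3L, list(c(1, 2, 1), c(2, 3, 2), c(3, 1, 2)))
  perm <- c(3L, 1L, 2L)
  expect_equal(canonical_certificate(tri[perm, perm]), canonical_certificate(tri))
  expect_false(canonical_certificate(mk_adj(3L, list(c(1, 2, 1), c(2, 3, 1), c(3, 1, 2)))) ==
                 canonical_certificate(mk_adj(3L, list(c(1, 2, 1), c(2, 3, 3)))))
  # certificate equality <=> exhaustive permutation isomorphism
  same_v <- outer(vapply(mats, nrow, integer(1L)), vapply(mats, nrow, integer(1L)), "==")
  for (a in seq_along(mats)) {
    for (b in seq_len(a)) {
      if (!same_v[a, b]) next
      expect_identical(certs[a] == certs[b],
                       isomorphic_bruteforce(mats[[a]], mats[[b]]),
                       info = sprintf("pair %d,%d", a, b))
    }
  }
})

test_that("graph matching handles hits, rule violations and the empty graph", {
  expect_equal(match_graph(matrix(0L, 0L, 0L)), "no_helices")
  # K_{1,3}: four odd-degree vertices, violates the realizability rule
  star <- mk_adj(4L, list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1)))
  expect_false(satisfies_realizability_rule(star))
  expect_equal(match_graph(star), "unmatched")
  expect_equal(match_graph(matrix(0L, 8L, 8L), catalog_set(4L)),
               "unmatched (oversized)")
})

test_that("realizability rule is equivalent to single-strand realizability (V<=4)", {
  # all connected loopless multigraphs on <= 4 vertices with multiplicities <= 4
  for (V in 2:4) {
    mmax <- if (V == 4L) 3L else 4L  # a 4-fold edge at V=4 always breaks the degree cap
    epairs <- utils::combn(V, 2L, simplify = FALSE)
    grid <- do.call(expand.grid, rep(list(0:mmax), length(epairs)))
    for (r in seq_len(nrow(grid))) {
      adj <- mk_adj(V, Map(function(e, m) c(e, m), epairs, as.integer(grid[r, ])))
      if (max(rowSums(adj)) > 4L) next     # cannot be realized; also pruned by rule
      if (!rnadual:::is_connected_adj(adj)) next
      expect_identical(has_single_strand_realization(adj),
                       satisfies_realizability_rule(adj),
                       info = paste("row", r, "V", V))
    }
  }
})

test_that("pseudoknot labels match the published counts and examples", {
  c2 <- enumerate_catalog(2L)
  expect_equal(c2$entries$pseudoknotted, c(FALSE, FALSE, TRUE)) # only 2_3
  c3 <- enumerate_catalog(3L)
  expect_equal(sum(c3$entries$pseudoknotted), 4L)
  expect_false(c3$entries$pseudoknotted[c3$entries$id == "3_5"])
  expect_true(c3$entries$pseudoknotted[c3$entries$id == "3_6"])
})

test_that("nested-forest oracle agrees with the realization-word search", {
  expect_equal(nested_unknotted_set(2L), c("2_1", "2_2"))
  for (V in 2:4) {
    cat_v <- enumerate_catalog(V)
    nested <- nested_unknotted_set(V, cat_v)
    pk_ids <- cat_v$entries$id[cat_v$entries$pseudoknotted]
    expect_equal(sort(setdiff(cat_v$entries$id, nested)), sort(pk_ids),
                 info = paste("V", V))
  }
})

test_that("identifier concordance translates only established V=4 indices", {
  expect_equal(published_id(c("1_1", "3_3", "4_13", "4_14")),
               c("1_1", "3_3", "4_13", "4_14"))
  expect_equal(published_id(c("4_15", "4_18", "4_26", "4_29")),
               c("4_16", "4_19", "4_27", "4_30"))
  expect_true(is.na(published_id("5_28")))
  expect_equal(published_id("no_helices"), "no_helices")
  expect_equal(id_index(c("4_19", "3_5")), c(19L, 5L))
})

test_that("catalog TSV export carries one row per entry", {
  txt <- write_catalog_tsv(enumerate_catalog(3L))
  lines <- strsplit(txt, "\n")[[1L]]
  expect_length(lines, 9L)  # header + 8 entries
  expect_match(lines[1L], "^id\tV\tn\t")
})
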