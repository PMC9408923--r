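test_that("interaction map applies the >1 base-pair threshold", {
  # chains A and B share exactly 1 pair: no interaction
  spec1 <- scenario_spec(chains = list(list(id = "A", len = 30L),
                                       list(id = "B", len = 30L)),
                         helices = list(list(a = "A", b = "B", bp = 1L),
                                        list(a = "A", b = "A", bp = 3L),
                                        list(a = "B", b = "B", bp = 3L)),
                         seed = 1L)
  s1 <- parse_structure(make_complex_scenario(spec1), format = "complex_tsv")
  im1 <- interaction_map(s1)
  expect_equal(im1[["A-1"]], character(0))

  # 2 shared pairs, dissimilar chains: mutual interaction
  spec2 <- scenario_spec(chains = list(list(id = "A", len = 30L),
                                       list(id = "B", len = 30L)),
                         helices = list(list(a = "A", b = "B", bp = 2L),
                                        list(a = "A", b = "A", bp = 4L)),
                         seed = 2L)
  s2 <- parse_structure(make_complex_scenario(spec2), format = "complex_tsv")
  im2 <- interaction_map(s2)
  expect_equal(im2[["A-1"]], "B-1")
  expect_equal(im2[["B-1"]], "A-1")
})

test_that("near-identical interacting copies are excluded as polymers", {
  spec <- scenario_spec(chains = list(list(id = "A", len = 30L)),
                        helices = list(list(a = "A", b = "A", bp = 5L)),
                        duplications = list(list(source = "A", id = "B",
                                                 mutations = 1L)),
                        seed = 3L)
  s <- parse_structure(make_complex_scenario(spec), format = "complex_tsv")
  sim <- chain_similarity(get_subchain(s, "A-1"), get_subchain(s, "B-1"))
  expect_gt(sim[["seq_identity"]], 0.92)
  expect_gt(sim[["struct_identity"]], 0.92)
  expect_equal(interaction_map(s)[["A-1"]], character(0))
  # the dimer separates into two hairpin substructures
  subs <- find_substructures(s)
  expect_length(subs, 2L)
  expect_equal(vapply(subs, function(x) x$graph_id, character(1L)),
               c("1_1", "1_1"))
  # without the polymer filter they would merge
  expect_length(find_substructures(s, similarity_threshold = 1), 1L)
})

test_that("substructure search follows the interaction closure", {
  # N interacts with {P1, O}, P1 with {Q, N}, O with {N}, Q with {P1}:
  # one substructure {N, O, P1, Q}
  spec <- scenario_spec(
    chains = list(list(id = "N", len = 40L), list(id = "O", len = 30L),
                  list(id = "P", len = 40L), list(id = "Q", len = 30L)),
    helices = list(list(a = "N", b = "P", bp = 3L),
                   list(a = "N", b = "O", bp = 3L),
                   list(a = "P", b = "Q", bp = 3L)),
    seed = 5L)
  s <- parse_structure(make_complex_scenario(spec), format = "complex_tsv")
  subs <- find_substructures(s)
  expect_length(subs, 1L)
  expect_equal(subs[[1L]]$members, c("N-1", "O-1", "P-1", "Q-1"))
  expect_equal(subs[[1L]]$category, "multiple_rna_subchains")

  # self-folded lone subchain -> singleton hairpin; unpaired lone subchain ->
  # singleton with no helices
  spec2 <- scenario_spec(chains = list(list(id = "A", len = 20L),
                                       list(id = "B", len = 12L)),
                         helices = list(list(a = "A", b = "A", bp = 4L)),
                         seed = 6L)
  s2 <- parse_structure(make_complex_scenario(spec2), format = "complex_tsv")
  subs2 <- find_substructures(s2)
  expect_length(subs2, 2L)
  expect_equal(vapply(subs2, function(x) x$graph_id, character(1L)),
               c("1_1", "no_helices"))
  expect_equal(subs2[[1L]]$category, "single_rna_subchain")
})

test_that("search equals union-find components and ignores subchain order", {
  for (seed in 1:60) {
    s <- random_scenario(seed)
    imap <- interaction_map(s)
    subs <- find_substructures(s, imap = imap)
    # partition of the subchain set
    members <- unlist(lapply(subs, `[[`, "members"))
    expect_setequal(members, s$subchains$id)
    expect_equal(anyDuplicated(members), 0L)
    # equivalence with the independent union-find oracle
    expect_equal(member_key(subs), uf_components(s, imap),
                 info = paste("seed", seed))
  }
  # explicit iteration-order invariance: reverse the subchain listing
  s <- random_scenario(17L)
  rev_rows <- rev(seq_len(nrow(s$subchains)))
  idx <- unlist(lapply(rev_rows, function(r) s$subchains$start[r]:s$subchains$end[r]))
  newpos <- integer(n_residues(s)); newpos[idx] <- seq_along(idx)
  s_rev <- complex_structure(
    s$residues[idx, c("chain", "molecule", "serial", "base")],
    cbind(newpos[s$pairs[, 1L]], newpos[s$pairs[, 2L]]), "reversed")
  expect_equal(member_key(find_substructures(s_rev)),
               member_key(find_substructures(s)))
})

test_that("categories reflect molecule types and member counts", {
  spec <- scenario_spec(
    chains = list(list(id = "L", len = 40L, molecule = "RNA"),
                  list(id = "N", len = 40L, molecule = "DNA"),
                  list(id = "M", len = 40L, molecule = "DNA")),
    helices = list(list(a = "L", b = "N", bp = 6L),
                   list(a = "M", b = "N", bp = 6L),
                   list(a = "L", b = "L", bp = 4L)),
    seed = 7L)
  s <- parse_structure(make_complex_scenario(spec), format = "complex_tsv")
  subs <- find_substructures(s)
  expect_length(subs, 1L)
  expect_equal(subs[[1L]]$members, c("L-1", "M-1", "N-1"))
  expect_equal(subs[[1L]]$category, "dna_containing")
  expect_equal(categorize_substructure("L-1", s), "single_rna_subchain")
  expect_equal(categorize_substructure(c("L-1", "N-1"), s), "dna_containing")
})

test_that("round-2 refinement splits oversized substructures along filters", {
  spec <- scenario_spec(
    chains = list(list(id = "B", len = 80L), list(id = "F", len = 50L),
                  list(id = "H", len = 50L)),
    helices = c(lapply(1:6, function(k) list(a = "B", b = "B", bp = 3L)),
                lapply(1:2, function(k) list(a = "F", b = "F", bp = 3L)),
                lapply(1:2, function(k) list(a = "H", b = "H", bp = 3L)),
                list(list(a = "B", b = "F", bp = 2L),
                     list(a = "F", b = "H", bp = 2L))),
    seed = 11L)
  s <- parse_structure(make_complex_scenario(spec), format = "complex_tsv")
  subs <- find_substructures(s)
  expect_length(subs, 1L)
  expect_equal(subs[[1L]]$graph_id, "oversized")
  expect_equal(subs[[1L]]$helix_count, 12L)

  filters <- data.frame(filter_name = c("f1", "f2", "f2", "f3"),
                        chain_id = c("B", "F", "H", "X"))
  refined <- refine_oversized(subs[[1L]], filters)
  expect_length(refined, 2L)
  expect_equal(lapply(refined, `[[`, "members"),
               list("B-1", c("F-1", "H-1")))
  expect_true(all(vapply(refined, `[[`, character(1L), "origin") == "round2"))
  # disjoint filter contributes nothing but is logged
  expect_match(paste(attr(refined, "log"), collapse = " "), "f3")
  # no refined group has more helices than its parent
  expect_true(all(vapply(refined, `[[`, integer(1L), "helix_count") <=
                    subs[[1L]]$helix_count))
  # overlapping filters produce no duplicate member sets
  filters2 <- rbind(filters, data.frame(filter_name = "f4", chain_id = "B"))
  refined2 <- refine_oversized(subs[[1L]], filters2)
  keys <- vapply(refined2, function(r) paste(r$members, collapse = "|"), character(1L))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("motif census conserves weights and splits categories", {
  structures <- list(parse_structure("((((....))))"),
                     parse_structure("((((...))))"),
                     parse_structure("(((((...)))))"),
                     parse_structure(">duplex\nGGGG&CCCC\n((((&))))"),
                     parse_structure("((..((....))..))"),
                     parse_structure("........"))
  subs <- unlist(lapply(structures, find_substructures), recursive = FALSE)
  cen <- motif_census(subs)
  expect_equal(cen$weight[cen$graph_id == "1_1"], 4L)
  expect_equal(cen$weight[cen$graph_id == "2_2"], 1L)
  expect_equal(cen$weight[cen$graph_id == "no_helices"], 1L)
  matched <- grepl("^[0-9]+_[0-9]+$", cen$graph_id)
  expect_equal(sum(cen$weight[matched]),
               sum(vapply(subs, function(x) grepl("^[0-9]+_", x$graph_id), logical(1L))))
  expect_equal(cen$weight,
               cen$count_single_rna + cen$count_multi_rna + cen$count_dna)
})
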