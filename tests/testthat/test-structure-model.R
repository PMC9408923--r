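test_that("dot-bracket parsing matches brackets layer by layer", {
  s <- parse_structure("((((....))))")
  expect_equal(nrow(s$subchains), 1L)
  expect_equal(n_residues(s), 12L)
  expect_equal(unname(s$pairs),
               cbind(1:4, c(12L, 11L, 10L, 9L)))

  # two bracket layers whose pairs interleave (hand-matched)
  s2 <- parse_structure("((((..[[[..))))..]]]")
  expect_equal(nrow(s2$pairs), 7L)
  expect_true(all(rbind(c(1L, 15L), c(4L, 12L), c(7L, 20L), c(9L, 18L)) %in% s2$pairs))

  # strand separator gives a two-chain duplex with inter-chain pairs
  s3 <- parse_structure("((((&))))")
  expect_equal(nrow(s3$subchains), 2L)
  expect_equal(s3$subchains$chain, c("A", "B"))
  expect_equal(nrow(s3$pairs), 4L)
  expect_true(all(s3$pairs[, 1L] <= 4L & s3$pairs[, 2L] >= 5L))
})

test_that("malformed input raises classed errors", {
  expect_error(parse_structure("((..)"), class = "rnadual_parse_error")
  expect_error(parse_structure("..))"), class = "rnadual_parse_error")
  # partner column inconsistency: 1 pairs 3 but 3 pairs 2
  bp <- "1 A 3\n2 C 0\n3 G 2"
  expect_error(parse_structure(bp, format = "bpseq"),
               class = "rnadual_integrity_error")
  # residue paired to itself
  expect_error(parse_structure("1 A 1\n2 C 0", format = "bpseq"),
               class = "rnadual_integrity_error")
  # keep_first_pair prunes non-reciprocal claims deterministically
  s <- parse_structure("1 A 4\n2 C 4\n3 G 0\n4 U 1", format = "bpseq",
                       keep_first_pair = TRUE)
  expect_equal(unname(s$pairs), cbind(1L, 4L))
})

test_that("subchains split at chain changes, serial gaps, and BREAK markers", {
  res <- data.frame(chain = "B", serial = c(1:10, 21:30))
  out <- split_subchains(res)
  sc <- attr(out, "subchains")
  expect_equal(sc$id, c("B-1", "B-2"))
  expect_equal(sc$length, c(10L, 10L))

  # five gap-separated runs in one chain -> B-1 .. B-5
  res5 <- data.frame(chain = "B", serial = c(1:5, 11:15, 21:25, 31:35, 41:45))
  sc5 <- attr(split_subchains(res5), "subchains")
  expect_equal(sc5$id, paste0("B-", 1:5))

  expect_equal(nrow(attr(split_subchains(data.frame(chain = "A", serial = 1:8)),
                         "subchains")), 1L)
  expect_error(split_subchains(data.frame(chain = "A", serial = c(1, 2, 2))),
               class = "rnadual_integrity_error")

  # explicit BREAK row in the complex table forces a split without a gap
  tsv <- paste(
    "chain\tmolecule\tserial\tbase\tpair_chain\tpair_serial",
    "A\tRNA\t1\tG\t\t", "A\tRNA\t2\tC\t\t",
    "A\tRNA\t\tBREAK\t\t",
    "A\tRNA\t3\tA\t\t", "A\tRNA\t4\tU\t\t",
    sep = "\n")
  s <- parse_structure(tsv, format = "complex_tsv")
  expect_equal(s$subchains$id, c("A-1", "A-2"))
})

test_that("dot-bracket writer round-trips pairs and subchain boundaries", {
  for (seed in 1:30) {
    st <- random_structure(1L + seed %% 6L, pk_probability = 0.5, seed = seed)
    back <- parse_structure(write_dotbracket(st), format = "dotbracket")
    expect_equal(unname(back$pairs), unname(st$pairs))
    expect_equal(back$subchains$length, st$subchains$length)
  }
  # H-type pseudoknot needs exactly two layers
  pk <- parse_structure("((((..[[[..))))..]]]")
  txt <- write_dotbracket(pk)
  expect_match(txt, "\\[\\[\\[")
  expect_equal(unname(parse_structure(txt)$pairs), unname(pk$pairs))
})

test_that("complex table writer round-trips including explicit breaks", {
  spec <- scenario_spec(chains = list(list(id = "B", len = 30L)),
                        helices = list(list(a = "B", b = "B", bp = 3L)),
                        breaks = list(list(chain = "B", after = 15L)),
                        seed = 4L)
  s <- parse_structure(make_complex_scenario(spec), format = "complex_tsv")
  back <- parse_structure(write_complex_tsv(s), format = "complex_tsv")
  expect_equal(unname(back$pairs), unname(s$pairs))
  expect_equal(back$subchains$id, s$subchains$id)
})

test_that("crossing detection finds interleaved pairs", {
  expect_false(has_crossing(parse_structure("((((....))))")))
  expect_true(has_crossing(parse_structure("((((..[[[..))))..]]]")))
  expect_false(has_crossing(parse_structure("((..))((..))")))
  # invariant to reversing the concat order of a single-subchain structure
  s <- parse_structure("((((..[[[..))))..]]]")
  expect_identical(has_crossing(s, rev(s$subchains$id)), has_crossing(s))
  expect_error(has_crossing(s, c("A-1", "A-1")), class = "rnadual_parse_error")
})

test_that("chain similarity is a symmetric alignment identity", {
  a <- list(sequence = "ACGUACGU", pairing = "pppp....")
  expect_equal(unname(chain_similarity(a, a)), c(1, 1))

  b <- list(sequence = "ACGUACGU", pairing = "........")
  ab <- chain_similarity(a, b)
  expect_equal(unname(ab[["seq_identity"]]), 1)
  expect_equal(unname(ab[["struct_identity"]]), 0.5)

  full <- list(sequence = "ACGU", pairing = "pppp")
  none <- list(sequence = "ACGU", pairing = "....")
  expect_equal(unname(chain_similarity(full, none)), c(1, 0))

  x <- list(sequence = "ACGU", pairing = "....")
  y <- list(sequence = "ACGA", pairing = "....")
  expect_equal(unname(chain_similarity(x, y)), c(0.75, 1))
  expect_equal(chain_similarity(y, x), chain_similarity(x, y))
})

test_that("parsers produce a matching (no residue in two pairs)", {
  for (seed in 1:20) {
    s <- random_scenario(seed)
    expect_lte(max(tabulate(s$pairs, nbins = n_residues(s))), 1L)
  }
})
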