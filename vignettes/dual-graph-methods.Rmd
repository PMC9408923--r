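---
title: "Dual graphs of nucleic-acid secondary structures: model, catalog and partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual graphs of nucleic-acid secondary structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnadual)
```

## The representation

RNA folds on itself through Watson–Crick (A-U, G-C) and wobble (G-U) pairs.
Runs of stacked pairs form *stems*; everything else is loop: hairpins,
bulges, internal loops, junctions, and — when a loop pairs with a region
outside its enclosing helix — *pseudoknots*. The dual graph coarse-grains a
structure by making each stem a vertex and each single-stranded connector
an edge:

* a junction segment or a pseudoknot strand is one edge;
* an internal loop or bulge has two strands, hence two parallel edges;
* a hairpin loop is a self-edge;
* dangling 5′/3′ ends contribute nothing.

Stem calling applies two smoothing rules before any edge is drawn: a 1-nt
bulge or a 1×1 internal loop is absorbed into the surrounding stem
(iterated to a fixed point, so chains of small bulges collapse), and stems
with fewer than two pairs after merging are discarded, their residues
reverting to unpaired. Two orderings of these rules are defensible; this
package merges first and thresholds second, so an isolated pair that stacks
across a 1-nt bulge onto a neighbouring run survives. Asymmetric 1-nt/2-nt
internal loops are *not* absorbed — only the exact 1-nt bulge and 1×1 loop
are. Merging never crosses a subchain boundary: both strands of a stem must
be continuous.

The construction itself is a strand traversal. For every subchain, the stem
side-intervals it hosts are sorted 5′→3′; each pair of consecutive visits
adds one edge between their stems (a self-edge when the two visits belong
to one stem). Zero-length segments — the strand opposite a bulge — still
count as a visit boundary, which is what makes a bulge produce two parallel
edges. The traversal handles pseudoknots and multi-chain complexes without
special cases, and yields two structural invariants that the test suite
fuzzes: every vertex obeys `deg(v) + 2·self_loops(v) ≤ 4`, and
`edges + self_loops = 2V − k` with `k` the number of subchains carrying at
least one visit.

## The catalog and its identifiers

Which multigraphs can a nucleic-acid strand actually realize? Model the
strand as a word visiting each stem exactly twice (once per side). The
adjacencies of the word are the graph's edges, so the word is an Eulerian
trail padded with hairpin visits, and a connected loopless multigraph has a
single-strand realization exactly when

1. every degree is ≤ 4,
2. the number of odd-degree vertices is 0 or 2 (the strand's ends), and
3. with no odd vertex, some vertex has degree < 4 (both ends must sit at
   one stem, which then has two slots spare).

`enumerate_catalog()` generates all such graphs exhaustively: connected
simple skeletons with maximum degree 4 are built by vertex augmentation and
deduplicated by a canonical certificate (iterated neighbourhood refinement
plus a lexicographic search over colour-preserving relabellings — exact at
these sizes), then edge multiplicities 1–4 are assigned by a degree-pruned
search and deduplicated through the skeleton's automorphism group. The
per-vertex counts are 1, 3, 8, 29, 110, 508 and 2551 for V = 1…7; the test
suite cross-checks V ≤ 4 against a brute-force enumeration with
permutation isomorphism, and verifies on the same range that the
realizability conditions coincide with an explicit search for realization
words. Enumeration is supported to V = 7; beyond that, matching reports
`"unmatched (oversized)"` — substructures that large are candidates for
refinement rather than for direct classification.

Identifiers `V_n` order the graphs of a fixed V by Laplacian spectrum
(`L = D − A` with integer multiplicities), compared lexicographically from
the Fiedler value up, with exact eigenvalue ties broken by the canonical
certificate; eigenvalues are rounded to 10 decimals before comparison. More
compact, better-connected graphs get larger `n`. This ordering reproduces
the historical library's identifiers entry for entry at V ≤ 3 and for the
first 14 four-vertex graphs. From there the historical four-vertex
numbering runs one ahead (its ids reach `4_30` for 29 graphs) — the legacy
catalog evidently carried an entry, later retired, between the graphs
ranked 14 and 15 here. The shipped concordance table
(`inst/extdata/published-id-concordance.tsv`, applied by `published_id()`)
pins every documented anchor: `4_13` and `4_14` unshifted, the
triangle-plus-double-pendant at `4_16`, the four-way junction at `4_19`,
the kissing-loop pseudoknot at `4_27`. Rows between anchors interpolate the
single shift and are flagged as such. For V ≥ 5 the historical ids descend
from a legacy enumeration order that no spectral sort reproduces (the
five-way junction, spectral rank 68, is historically `5_2`), so the
concordance deliberately claims nothing there and `published_id()` returns
`NA`: computed ids are the package's working vocabulary, and the
concordance is the explicit, auditable bridge to the literature's.

## Pseudoknot labels

A catalog graph is *pseudoknotted* when every strand that folds into it
must cross itself: no realization word has a noncrossing chord diagram.
The label is decided by exact search over stack-discipline words (open any
unopened stem, or close the most recently opened one), consuming edge
multiplicities as adjacencent tokens; it is exact for V ≤ 6 and memoised
per certificate, and `NA` above that bound rather than a guess. An
independent oracle — enumerate ordered rooted forests of stems, map each to
its dual graph (sole child → double edge; k ≥ 2 children → junction cycle;
consecutive roots → unit edge), and collect what is reachable — must agree
with the word search on the full catalog at V ≤ 4, and does. One useful
consequence, verified on all V ≤ 5 graphs: a graph is pseudoknotted exactly
when one of its biconnected blocks is, which is the formal sense in which
block partitioning "keeps pseudoknots intact". (Not every pseudoknotted
graph is itself biconnected — a triple edge with a pendant bridge is
separable — so preservation is a statement about blocks, not about the
whole graph.)

## Substructure search

Multi-chain complexes are analysed at the level of *subchains*: maximal
continuous residue runs, split at chain changes, serial-number gaps, and
explicit break markers. Two subchains interact when they share **more than
one** base pair. Interacting pairs whose sequence *and* 2D-structure
identity both exceed 0.92 are excluded from the relation — crystallographic
packing of near-identical copies would otherwise fuse biological units into
polymers. Substructures are the transitive closures of the remaining
relation, computed by the published closure loop and verified against
union-find connected components on 200 seeded random scenarios; each
subchain lands in exactly one substructure, including self-folded
singletons and helix-free single strands (reported as `no_helices`).

Choices the literature leaves open, decided here:

* **Similarity metric.** Global alignment maximising matches (match +1,
  mismatch/gap 0); identity = matches / alignment length, structure
  identity = agreeing pairing states / alignment length. Ties prefer the
  diagonal, and the argument pair is ordered canonically first, making the
  measure symmetric. Both thresholds are strict and must be exceeded
  jointly for exclusion. The 0.92 threshold itself is the field's
  polymer-screening convention and is configurable.
* **Exclusion symmetry.** The polymer criterion is evaluated once per
  unordered pair, keeping the interaction relation symmetric and the
  closure well defined.
* **Sub-threshold contacts.** After grouping, *all* base pairs among the
  members — including single-pair contacts below the grouping threshold —
  are kept for graph construction; the threshold gates grouping only.
* **Seeds join their own substructure.** The closure starts from
  `{x} ∪ Y_x`, not `Y_x` alone; otherwise lone self-folded subchains would
  never be emitted.

Substructures with more than 9 helices are not discarded but marked
`oversized` and passed to a second round: each *filter group* (a set of
representative chain ids, as in curated non-redundant chain lists) selects
the member subchains of those chains, pairs leaving the selection are
dropped, and the search reruns on the restriction. Refined groups within
the 9-helix bound are collected, identical member sets from overlapping
filters deduplicated (first filter wins, in input order), and still-too-
large groups logged and dropped.

## Partitioning and subgraph inventories

Articulation points and biconnected blocks are computed on the multigraph
(via igraph's depth-first machinery; a vertex-deletion oracle re-derives
the articulation set on every catalog graph V ≤ 5 in the tests). Parallel
edges make their endpoints biconnected, so intertwined pseudoknots and
junction cycles are never cut; bridges become 2-vertex unit blocks;
self-loops stay outside all blocks as per-vertex hairpin annotations, and
likewise never enter catalog matching — forced, because the single
one-vertex catalog entry must cover hairpins and loop-free duplexes alike.

The subgraph inventory generalises "combine adjacent blocks" to every
connected subtree of the block-cut tree, from single blocks up to the full
graph (included as a subgraph of itself) — the only reading under which
partitioning offers "different levels of division". Inventories are
filtered to 2–9 vertices and matched to the catalog. The subgraph census
counts, for each id, the number of substructures containing it at least
once (a flag switches to occurrence counting, the other defensible
semantics).

## Synthetic data

The generator inverts the construction: a realization word is turned into a
structure with 4-bp stems and 4-nt loops — safely above both smoothing
thresholds, so the emitted structure's dual graph is exactly the word's
graph. Catalog entries are realized through a noncrossing word when
unknotted and a crossing one otherwise, giving labelled fixtures for the
pseudoknot tests; the full V ≤ 4 catalog plus 50 sampled V = 5 entries
round-trip through realize → write → parse → build → match. Multi-chain
scenarios (interaction closures, DNA hybrids, chain breaks, near-identical
polymer copies with a configurable number of point mutations) are assembled
from explicit directives with non-overlapping pairing blocks, so every
generated table is a valid matching by construction; chain lengths default
to 60 nt and helix blocks to 1–4 bp, the scale of the contacts the search
must discriminate.

What the generator does not emulate: thermodynamic plausibility of
sequences (bases are random, pairs are positional), non-canonical pair
geometry, base triples (inputs with multiplets are rejected, or pruned
deterministically under an explicit flag), and the experimental-resolution
artefacts that produce chain breaks in real data (breaks here are exact
directives). Green tests therefore certify the combinatorial machinery, not
2D-structure extraction from experimental coordinates, which sits upstream
of this package's remit.

## Numerical choices and problem sizes

Eigenvalues are rounded to 1e-10 before lexicographic comparison; residual
ties fall back to the certificate, so id assignment is deterministic.
Dot-bracket output assigns crossing pairs to layers greedily, first-fit
over `()[]{}<>` then `Aa…Zz`, and errors beyond 30 layers. The word
searches memoise per certificate and prune by stack discipline and edge
capacity. The default test run enumerates catalogs to V = 7 (seconds on one
CPU), fuzzes 150 structures for the slot bound, 500 nested fixtures for the
unknotted property, and 200 random scenarios for the search equivalence —
sizes chosen to exercise every code path while keeping the suite
interactive.

## Known limitations

* No 3D parsing, pair annotation from coordinates, or Leontis–Westhof
  classes: secondary structure is taken as given.
* The catalog is exhaustive only to V = 7 here (V = 8–9 are a compute
  question, not a correctness one); oversized graphs are reported, not
  classified.
* Historical-id concordance is established for V ≤ 4 only; elsewhere
  computed ids and historical ids are different vocabularies.
* Pseudoknot labels above V = 6 are `NA` by design.
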