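---
title: "Masking GC-biased signal in gene-family phylogenetics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masking GC-biased signal in gene-family phylogenetics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomask)
```

## The problem

Plant gene families such as the PIN auxin transporters and the ACC oxidases
are routinely analyzed with amino-acid distance methods, which amplify
convergent similarity. A specific, well-characterized source of convergence
in these data is compositional: grass (monocot) genes carry a strong
GC mutational bias, most visible at third codon positions (GC3 commonly
above 50%). Two unrelated GC-rich lineages share states not because of
common ancestry but because their mutational processes pull them toward the
same composition. An optimality criterion that counts shared states as
evidence will tend to group them.

phylomask implements a family of codon-aware alignment transformations that
remove the channels through which such a bias can act, together with the
parsimony machinery needed to analyze the transformed alignments with their
ambiguity semantics intact, and a simulator that reproduces the artifact so
every claim in the package is testable end to end.

## The transformations

Starting from a back-translated codon alignment (each aligned amino acid
replaced by its original codon, gaps becoming `---`):

* `strip_third_positions()` removes the most bias-exposed positions
  entirely.
* `mask_gc_to_n()` replaces every G and C with `N` ("any nucleotide"), so
  only A/T states carry signal. A↔T contrasts cannot be generated by a
  GC-directed bias, while shared A/T states still inform the tree.
* `serine_mask()` keeps only first and second positions of serine codons.
  Serine is unique: its codons (TCN, AGT, AGC) constrain position 1 to
  {T, A} and position 2 to {C, G}. A T/A contrast at position 1 and a C/G
  contrast at position 2 are both composition-neutral: swapping a genome
  toward GC changes neither a T into an A nor a C into a G preferentially
  at these positions.
* `to_question_marks()` widens `N` and `-` to `?` ("any nucleotide or
  gap"), deliberately discarding gap information to mimic programs that
  treat gaps as missing data.
* `trim_gappy_blocks()` removes alignment columns whose gap fraction
  exceeds one half (gaps are allowed in up to half of the rows), then
  removes surviving runs shorter than `min_block` columns, and replaces
  residual gaps with `N`. This is a deliberately light two-parameter block
  trimmer: the full conservation heuristics of dedicated trimming programs
  are out of scope, because gappy-region removal is the only behaviour the
  workflow relies on.

`flag_suspect_sequences()` screens for pseudogene-like entries before any
tree search: an ungapped length at most half the median length of the other
copies, or a terminal branch at least twice as long as the branch to its
sister group. The length criterion uses a leave-one-out median so that a
single truncated copy cannot drag the reference point toward itself.

## Ambiguity semantics in the parsimony engine

The distinction between `N` and `?` is load-bearing. `encode_matrix()` maps
every cell to a state set over the ordered alphabet A, C, G, T and — under
`gap_mode = "fifth_state"` — the gap:

* `N` is {A, C, G, T}: any nucleotide, but *not* a gap. Masked positions
  keep their gap information.
* `?` is {A, C, G, T, gap}: any nucleotide or a gap.
* `-` is the gap state under `fifth_state`; under `gap_mode = "missing"`,
  gap, `N` and `?` all collapse to {A, C, G, T}, reproducing how
  likelihood programs treat indels.

`fitch_length()` scores binary trees by the set-based Fitch pass, which is
exact for unit-cost unordered characters with set-valued leaves;
`sankoff_length()` is the unit-cost dynamic program, generalized to
multifurcations, and serves as an independent cross-check (the test suite
verifies exact agreement on hundreds of random instances, plus agreement
with phangorn's Fitch implementation on unambiguous data). Relaxing states
can only remove constraints, so `gap_mode = "missing"` never scores a tree
longer than `fifth_state` on the same data; this monotonicity is tested.

## Tree search

`heuristic_search()` uses the classical recipe: seeded random-addition
Wagner builds (`wagner_build()`), hill-climbing branch swapping (TBR by
default, SPR optionally), pooling of all trees that attain the best length,
collapsing of zero-length branches (an internal branch is collapsed when
contracting it into a polytomy leaves the parsimony length unchanged,
repeated to closure), and topological deduplication via canonical
bipartition sets. Proprietary composite strategies of parsimony programs
(sectorial searches, ratchet, drift, tree fusing) are not reimplemented;
many independent builds plus TBR is the transparent approximation, and the
build count is the knob the user controls. `exhaustive_search()` enumerates
all unrooted topologies for up to nine taxa and is the oracle against which
the heuristic is validated (50 random 7-taxon matrices per acceptance run,
both gap modes; agreement is required to be exact).

`strict_consensus()` normalizes rootings and keeps exactly the shared
bipartitions. `bootstrap_support()` resamples sites with replacement, runs
a reduced-effort search per pseudoreplicate, and reports the percentage of
pseudoreplicate consensuses containing each bipartition. All stochastic
operations take explicit integer seeds and are bitwise reproducible.

## Ancestral reconstruction of the morphology character

PIN proteins are coded 1–5 (long; short; reduced central loop; C-terminal
TMDs only; N-terminal TMDs only), unordered, unit cost.
`mpr_reconstruct()` runs the Sankoff recursion over the internal nodes of
the *unrooted* topology: a degree-2 root contributes no information for an
unordered character, so it is collapsed, which makes the minimum cost, the
per-node MPR sets and the reconstruction count independent of root
placement (the root argument only anchors the traversal, conventionally at
the bryophyte copies). Polytomies are handled by summing the recursion over
all children, so strict-consensus trees can be traced directly. The number
of equally parsimonious reconstructions is counted exactly by a product-sum
over optimal backpointers — ambiguous leaves contribute their cheapest
resolution but are not enumerated as separate reconstructions — and
`enumerate_reconstructions()` lists them explicitly below a cap, verifying
each against the direct edge-count cost. The test suite checks minimum
cost, MPR sets and counts against exhaustive enumeration over all
5^(internal nodes) assignments on a hundred random trees.

## The TMD classifier

`classify_pin()` reduces a TMD layout to three features: the central
hydrophilic loop (the largest gap between consecutive TMDs), and the
N-terminal and C-terminal TMD blocks it separates. Proteins whose TMDs all
end within the N-terminal half are type 5, those whose TMDs all start in
the C-terminal half are type 4; otherwise the loop length decides long
(≥ 200 aa), reduced (100–199 aa) or short (< 100 aa). The published
classification criteria are qualitative; the 200/100 aa cutoffs and the
one-half terminal fraction are this package's quantitative defaults,
exposed in `classifier_config()`. Two documented overrides
(`pin_default_overrides()`) force genes that are sequence-wise ordinary
long forms, but were predicted with only an N-terminal TMD block, to
type 1; overrides are applied last and flagged in the output. TMD interval
coordinates (not counts) are the canonical input: a TMD count alone cannot
separate the types — five TMDs occur in types 1, 2, 4 and 5 of the
packaged survey — so counts-only input is rejected.

The packaged survey (`pin_morphology_survey()`, 151 PIN proteins) prints
lengths, TMD counts and types but not interval coordinates;
`pin_survey_layouts()` reconstructs synthetic layouts consistent with the
printed columns via `simulate_tmd_protein()` under fixed seeds, and the
regression test requires the classifier to reproduce every printed score,
overrides included. These layouts are stand-ins for the original TMD
predictions, not the predictions themselves.

## The simulator and what it does (and does not) show

`simulate_alignment()` evolves codons site-independently down a tree under
an F81-type process: with probability `1 - exp(-beta * t)` a site is
redrawn from the branch's stationary composition. First and second
positions use a uniform composition on every branch; third positions use a
composition with GC content `gc3_default`, except on branches whose
descendant leaves are all in `biased_taxa`, where the equilibrium GC is
`gc3_biased`. This is the minimal mechanism that produces a
lineage-specific GC3 substitution bias; it deliberately omits codon
selection (dN/dS), rate heterogeneity across sites, indels, and
nonstationarity at first/second positions, so simulated alignments are
gap-free and the gap-handling code paths are exercised by constructed
fixtures instead. Passing tests therefore demonstrate that the
masking transforms remove exactly the compositional channel of
convergence; they do not certify behaviour under selection-driven
convergence or alignment error in real data.

### The packaged convergence regime

`convergence_default_config()` fixes the study conditions for the
demonstration: an eight-leaf balanced tree, internal branches of 0.04 and
terminal branches of 1.0 expected substitutions per site (at relative rate
1), relative position rates 0.3/0.2/3.0, 2000 codons, and two non-sister
leaves (`t3`, `t6`) with third-position equilibrium GC 0.8 against 0.5
elsewhere. The regime was chosen from the mechanism: with third positions
effectively saturated on terminal branches (exposure 3 substitutions/site),
the expected excess of shared third-position states between the two biased
leaves (≈ 0.09 per codon) exceeds the parsimony support of the two short
cherry edges that must be overturned to group them, so the unmasked
analysis is systematically misled, while the masked analysis (third
positions stripped, G/C → N) retains only the composition-neutral signal
and converges on the true tree as sites accumulate. At these settings the
effect is large and stable across seeds: in 20 replicates the unmasked
search groups the biased pair in roughly three quarters of replicates and
the masked search in none, with clearly lower mean Robinson–Foulds
distance to the true tree for the masked treatment.
`convergence_experiment()` reports per-replicate groupings and RF
distances; the acceptance script adds a one-sided sign test.

## Numerical and interface choices

* Composition summaries treat genes, not columns, as sampling units, with
  normal-approximation 95% intervals (mean ± 1.96 sd/√n); a single-gene
  group reports a mean with `NA` interval. Frequencies exclude gaps and
  ambiguity codes from the denominator, and a gene × position cell with
  nothing countable is dropped from summaries rather than imputed.
* The group comparison of GC percentages is a Welch (unequal-variance)
  two-sample t-test; the equal-variance assumption is not defensible for
  GC content across gene sets, and the choice is recorded in the output.
  Two constant equal groups return t = 0, p = 1 rather than an error.
* All user-facing coordinates (TMD intervals, kept-column reports) are
  1-based inclusive, matching how biologists read tables; 0-based
  arithmetic stays internal.
* FASTA input is uppercased and U → T normalized; `N`, `?`, `X`, `-` and
  IUPAC ambiguity codes are the only non-ACGT characters admitted, and
  violations are reported with record and position.
* TNT export writes `N` as `N`, never silently as `?`: the two symbols
  mean different things in this package and in the target program.
* Wagner builds break ties by a seeded uniform draw; searches and
  bootstraps derive per-replicate seeds from the user seed, so any
  reported tree count ("85 equally parsimonious trees"-style claims made
  with this package) is reproducible from the seed alone.
* Problem sizes in the packaged tests — 7-taxon matrices against the
  exhaustive oracle, 100-replicate invariant batches, 20-replicate
  convergence runs — are the scales at which the oracles are exact and the
  randomized checks stable; they are package choices, documented here.

## Known limitations

* The search is a transparent build-and-swap heuristic; on large matrices
  it will need more builds than a ratchet-style search would to reach the
  same optima, and the equal-length tree harvest is capped (`max_trees`).
* `exhaustive_search()` stops at nine taxa by design.
* The Gblocks-style trimmer implements only the gap-fraction and minimum
  block-length rules, not conservation scoring.
* The simulator's bias acts on whole lineages (edges all of whose
  descendants are biased); paraphyletic bias patterns must be expressed by
  listing the affected leaves.
* The classifier trusts its TMD intervals; predictions from hydropathy
  servers carry their own error, which no threshold choice can undo.
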