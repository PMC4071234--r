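# phylomask

Convergence-aware parsimony phylogenetics for GC-biased codon alignments.

## The problem

Gene-family phylogenies of plant developmental genes — the PIN auxin
transporters and the ACC oxidases (ACOs) are the motivating cases — are
distorted by a compositional artifact: grass (monocot) genes carry a strong
GC mutational bias, concentrated at third codon positions (GC3 often above
50%). Two unrelated GC-rich lineages come to share states because their
substitution processes pull them toward the same base composition, and any
optimality criterion that counts shared states as evidence of common
ancestry will tend to group them. phylomask is a toolkit for building trees
that are immune to this channel of convergence, for people who analyze
gene families from coding sequence:

* **Masking transforms** on codon alignments: `back_translate()` (protein
  alignment + CDS → codon alignment), `strip_third_positions()`,
  `mask_gc_to_n()` (G/C → N, "any nucleotide"), `serine_mask()` (keep only
  serine's first/second codon positions, which can only be T/A and C/G
  respectively and are therefore composition-neutral),
  `to_question_marks()` (N/gap → ?, "any nucleotide or gap"),
  `trim_gappy_blocks()` (gaps allowed in up to half the rows), and
  `flag_suspect_sequences()` (pseudogene screen: half-length copies,
  double-length terminal branches).
* **A maximum-parsimony engine** whose ambiguity semantics match the
  masking: `encode_matrix()` distinguishes N = {A,C,G,T} from
  ? = {A,C,G,T,gap}, with the gap scored as a fifth state or as missing
  data; `fitch_length()` / `sankoff_length()` scoring, `wagner_build()`
  random-addition starts, `heuristic_search()` (TBR/SPR),
  `exhaustive_search()` (≤ 9 taxa, the oracle), `strict_consensus()`,
  `bootstrap_support()`, `collapse_zero_branches()`.
* **Ancestral reconstruction** of the unordered five-state PIN morphology
  character (`mpr_reconstruct()`), with the full most-parsimonious
  reconstruction set per node, an exact count of equally parsimonious
  reconstructions, and explicit enumeration (`enumerate_reconstructions()`,
  `paint_tree()`).
* **A TMD-layout classifier** (`classify_pin()`) assigning PIN morphology
  types 1–5 (long / short / reduced loop / C-terminal TMDs only /
  N-terminal TMDs only) from protein length and transmembrane-domain
  intervals, with the two documented per-gene overrides; a packaged
  151-protein survey (`pin_morphology_survey()`) serves as its regression
  fixture.
* **A simulator** (`simulate_alignment()`) evolving codons down a known
  tree with lineage-specific third-position GC bias, and
  `convergence_experiment()`, which demonstrates on simulated data that
  the unmasked analysis groups the biased lineages while the masked
  analysis recovers the true tree.

The parsimony criterion is the minimum number of unordered state changes
s(T) = Σ_sites min changes on tree T, computed by the set-based Fitch pass
(exact for set-valued leaf ambiguity under unit cost) and cross-checked by
unit-cost Sankoff dynamic programming, which also generalizes scoring to
polytomies.

## Worked example

```r
library(phylomask)

aa  <- seq_set(c(AtPIN1 = "MSLS-K", OsPIN1a = "MSLSAK", PpPIN1A = "MTLS-K"),
               "amino_acid")
cds <- seq_set(c(AtPIN1 = "ATGTCACTTTCTAAA", OsPIN1a = "ATGAGCCTGAGCGCGAAG",
                 PpPIN1A = "ATGACGTTAAGTAAG"), "nucleotide", aligned = FALSE)
(aln <- back_translate(aa, cds))
#> <codon_alignment> 3 taxa x 6 codons
#> <seq_set> 3 nucleotide sequence(s), aligned (18 columns)
#>   AtPIN1               ATGTCACTTTCT---AAA
#>   OsPIN1a              ATGAGCCTGAGCGCGAAG
#>   PpPIN1A              ATGACGTTAAGT---AAG
```

Each aligned residue became its original codon and the protein gap became
`---`, so the nucleotide alignment inherits the protein alignment. The
GC-masked alignment keeps positions 1–2 only and hides every G and C:

```r
mask_gc_to_n(strip_third_positions(aln))
#> <seq_set> 3 nucleotide sequence(s), aligned (12 columns)
#>   AtPIN1               ATTNNTTN--AA
#>   OsPIN1a              ATANNTANNNAA
#>   PpPIN1A              ATANTTAN--AA
```

Only A/T states remain informative; `N` is "any nucleotide" (gap
information survives), so a GC-directed bias can no longer generate shared
states. The serine-only transform is stricter still — non-serine codons
become `NN` and only serine's constrained first/second positions are kept
(`TC` for TCN codons, `AG` for AGT/AGC):

```r
unclass(serine_mask(aln))[1:3]
#>         AtPIN1        OsPIN1a        PpPIN1A
#> "NNTCNNTC--NN" "NNAGNNAGNNNN" "NNNNNNAG--NN"
```

The simulator reproduces the artifact these transforms target. Under the
packaged configuration (two non-sister leaves, `t3` and `t6`, with
third-position equilibrium GC 0.8 against 0.5 elsewhere), realized GC3 per
gene shows the two biased lineages clearly:

```r
cfg <- convergence_default_config(); cfg$n_codons <- 300L
sim <- simulate_alignment(cfg, seed = 1)
gc_percent(sim$alignment, positions = 3)
#> # A tibble: 8 x 2
#>   gene     gc
#> 1 t1    0.553
#> 2 t2    0.48
#> 3 t3    0.793   <- biased
#> 4 t4    0.463
#> 5 t5    0.53
#> 6 t6    0.847   <- biased
#> 7 t7    0.553
#> 8 t8    0.507
```

`convergence_experiment()` then runs the same parsimony search on the raw
and on the masked alignment of each replicate and reports whether the
biased pair was grouped and the Robinson–Foulds distance to the true tree;
at the packaged scale the unmasked analysis groups `t3 + t6` in most
replicates and the masked analysis in none.

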