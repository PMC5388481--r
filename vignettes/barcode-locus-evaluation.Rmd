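---
title: "Evaluating candidate DNA barcode loci: methods and design notes"
author: "barcodeEval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating candidate DNA barcode loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeEval)
```

## The problem

A DNA barcode locus is useful for species identification when specimens of
the same species are genetically closer to one another than to any specimen
of another species. For a candidate locus this package quantifies that
property three ways, the way barcoding studies conventionally do:

1. **Barcode-gap analysis.** For each species, the maximum pairwise distance
   among its specimens (`D_intra`) is compared with the minimum distance from
   any of its specimens to any heterospecific specimen (`D_NN`, the
   nearest-neighbour distance). A species shows a *barcode gap* when
   `D_NN > D_intra` (strict); a locus shows a *clear* gap when the smallest
   `D_NN` across species strictly exceeds the largest defined `D_intra`, i.e.
   the two distributions do not overlap.
2. **Tree-based monophyly.** A neighbour-joining (NJ) tree is built from the
   distance matrix and each species is tested for monophyly — in unrooted
   terms, whether a single edge separates exactly that species' tips from
   everything else. Nonparametric bootstrap over alignment columns attaches a
   support percentage to each bipartition; monophyly with support above a
   threshold (70% by default) counts as *confirmed*.
3. **Multilocus combinations.** Loci can fail in complementary ways (one
   locus amplifies a species the other cannot, or resolves a species pair the
   other collapses). All subsets of 2-5 loci are therefore re-analysed over
   the specimens shared by every member of the subset, on the column-wise
   concatenation of the per-locus alignments.

## Distance models

Two distances are computed over *comparable sites* — alignment columns where
both sequences carry an unambiguous nucleotide (A, C, G, T). Gaps and IUPAC
ambiguity codes are removed **pairwise** by default; complete deletion
(dropping every column containing any non-ACGT symbol) is available where a
common site set across all specimens is preferred.

* the **p-distance**, the proportion of mismatching comparable sites; and
* the **Kimura 2-parameter (K2P) distance**,
  `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`,
  where `P` and `Q` are the transition (A<->G, C<->T) and transversion
  proportions. K2P corrects for multiple hits and always dominates the
  p-distance of the same pair.

The K2P correction is undefined when `1 - 2P - Q <= 0` or `1 - 2Q <= 0`
(saturation) or when no comparable sites remain. Such pairs are stored as
missing and listed in `undefined_pairs` — they are excluded from gap
summaries and reported loudly rather than silently dropped, because an
excluded pair can only *remove* candidates from a `D_NN` minimum. Distances
are kept as proportions internally and rendered as percentages with two
decimals only at report time; all comparisons happen at full precision.

## Alignment statistics

Per locus the package reports aligned length, the number of variable sites
(at least two distinct unambiguous states in a column), parsimony-informative
sites (at least two states each carried by at least two sequences), and indel
events. Ambiguity codes never contribute to state counts — the conservative
reading when the original counting software is unspecified. "One indel
event" is defined here as a distinct maximal gap run keyed by its (start,
end) columns, so a deletion shared identically by several sequences counts
once; a per-sequence-run convention is available
(`locus_stats(x, indels = "per_sequence")`) because published indel counts
rarely state their convention and the two can differ substantially.

## Neighbour joining, bootstrap, monophyly

NJ follows the standard Saitou-Nei agglomeration on the distance matrix,
joining the pair minimising `Q(i,j) = (n-2) d(i,j) - r_i - r_j`. Two
numerical policies make the output reproducible and well-defined:

* **Ties** in `Q` are broken by the smallest (row, column) index pair in the
  current cluster list, so degenerate inputs (identical sequences, all-zero
  matrices) give one deterministic tree.
* **Negative branch-length estimates**, which NJ can produce on non-additive
  matrices, are clamped to zero; the total clamped amount is kept in
  `attr(tree, "neg_deficit")` so the distortion is visible. On additive
  matrices NJ is exact and the clamp never fires.

Specimens involved in undefined distances are excluded from tree building
for that locus (greedily, most-involved first) with the roster attached to
the tree — this mirrors the per-locus specimen dropout any multi-locus
study exhibits.

Bootstrap supports are attached to the edges of the *full-data* tree:
columns are resampled with replacement, the tree is rebuilt per replicate,
and each internal edge receives the percentage of replicates containing the
same bipartition. Replicates in which resampling makes some distance
undefined are dropped and counted (a warning fires above 10%). A replicate
tree lacking a full-data bipartition simply contributes nothing to that
edge — standard frequency counting. Supports live on the full-data tree
rather than on a consensus topology because the object of interest is
confidence in the clusters of the reported tree.

Monophyly testing works on any tree with tip labels, including imported
Newick trees: externally estimated maximum-likelihood topologies can be read
with `read_tree()` and scored with `test_monophyly()` without this package
re-implementing ML inference. Likelihood-based tree estimation is
deliberately out of scope — distance methods carry the analysis here, and
imported trees cover corroboration.

With exactly two species in an unrooted tree, one species forms a
bipartition if and only if the other does; "one species nesting inside
another" is only observable as asymmetric monophyly when at least a third
tip lies outside both, which is how the tests exercise that case.

## Multilocus combinations

Combinations use the **shared-specimen intersection**, not a
missing-data supermatrix: a specimen enters a combination only if it was
sequenced at every member locus. Concatenation is column-wise in
alphabetical locus order with the locus -> column-range partition retained
for provenance (distances are computed unpartitioned). Subsets with fewer
than 3 shared specimens or fewer than 2 species are skipped with a logged
reason rather than producing degenerate trees; both thresholds are
arguments. Arities 2-5 are analysed by default; the full six-locus
combination is supported but off by default.

## The simulator

`simulate_dataset()` exists so that every stage is testable with known
truth. It draws a uniform root sequence per locus, evolves it along a
species tree under a two-rate (transition/transversion, ratio `kappa`)
substitution process — the same K2P model the distance engine assumes, so
parameter-recovery checks are exact in expectation — and then evolves each
specimen from its species sequence along a terminal branch of
`intraspecific_scale / 2`, giving conspecific pairs an expected divergence
of `intraspecific_scale`. Within-species structure is therefore a star: the
simplest model consistent with summarising species by a maximum
intraspecific distance. Real intraspecific structure (clonal lineages,
geographic substructure) is richer than a star and is *not* emulated;
passing tests demonstrate correctness of the machinery, not robustness to
such structure. Dropout is an independent Bernoulli trial per (specimen,
locus) with per-(species, locus) success probabilities. Optional indels are
placed as species-shared deletion runs so matrices stay aligned.

`study_fixture()` encodes the study design the package ships as its working
example: 66 specimens across 12 Australian grass species (5 invasive, 7
native), six loci with realistic aligned lengths (356-838 nt), and
per-(species, locus) dropout probabilities set to published PCR success
rates — including a locus amplifying everything (the *atpF* analogue, all
probabilities >= 0.39) and a nuclear locus failing for 9 of 12 species (the
ITS analogue). The species tree places two congeners (*Nassella* analogue)
at 0.005 substitutions/site — deliberately below a resolvable gap — while
every other species pair diverges at 0.02 or more; the within-species scale
is 0.002. These values are the fixture's design and are not revisited:
interspecific divergences span roughly 0.5-18% and intraspecific distances
about 0.2%, inside the ranges such studies report.

## Parameter defaults

| Parameter | Default | Meaning |
|---|---|---|
| `model` | `k2p` | distance model for gaps and trees (`p` available; both can be computed) |
| `deletion` | `pairwise` | site removal for gaps/ambiguity, per pair |
| `reps` | 1000 | bootstrap replicates; 0 = trees without supports |
| `support_threshold` | 70 | percent support confirming monophyly |
| `arities` | 2:5 | combination sizes analysed |
| `min_shared` / `min_species` | 3 / 2 | viability floor for a combination |
| `kappa` | 3 | simulator transition/transversion rate ratio |

The bootstrap default of 1000 replicates and the 70% reporting threshold
follow the conventions of the barcoding literature this workflow reproduces.
The package's own test suite runs the simulation-recovery checks at 100
bootstrap replicates over 100 simulated datasets — sizes chosen so the full
suite stays interactive while the binomial margins remain decisive — and
verifies that species whose design nearest-neighbour divergence is at least
ten times the intraspecific scale are recovered monophyletic with support
above 70% in at least 95% of runs.

## Determinism

All randomness (simulation, bootstrap, combination bootstraps) flows from
one integer seed; identical configuration and seed give byte-identical JSON
summaries, Newick files and FASTA output. The JSON summary's structure is
described by a schema shipped at `inst/extdata/summary.schema.json`;
`validate_summary()` performs a structural check against it.

## Known limitations

* Distances other than p/K2P (gamma-corrected, GTR) and model selection are
  out of scope, as is ML/Bayesian tree inference (import trees instead).
* The gap criterion is the strict `D_NN > D_intra`; equality counts as no
  gap. Species represented by one specimen have undefined `D_intra` and are
  reported `N/A`, while still contributing to other species' `D_NN`.
* The simulator's star model of intraspecific variation understates the
  within-species distance spread of clonal or strongly structured species.
* Indel-event counts depend on the chosen convention; cross-study
  comparisons of indel numbers should state it.
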