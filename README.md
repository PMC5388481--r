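# barcodeEval

Tools for deciding whether candidate DNA barcode loci can tell species
apart. The package is aimed at molecular ecologists and biosecurity workers
who have per-locus aligned sequence matrices (for example Sanger consensus
sequences of plastid or nuclear markers across invasive and native grasses)
plus a specimen table, and who need the standard battery of barcoding
evidence: alignment statistics, distance matrices, barcode-gap analysis,
bootstrapped neighbour-joining trees, species monophyly tests, and
multilocus combination analyses.

## What it computes

**Distances.** Pairwise p-distance and Kimura 2-parameter distance over
comparable sites (pairwise deletion of gaps/ambiguities by default):

    d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)

with `P` the transition and `Q` the transversion proportion. Saturated pairs
(non-positive log argument) are recorded as undefined, never silently
dropped.

**Barcode gap.** Per species, the maximum intraspecific distance `D_intra`
versus the minimum nearest-neighbour distance `D_NN` over individual
heterospecific pairs. A species shows a gap when `D_NN > D_intra` (strict);
a locus shows a clear gap when `min(D_NN)` across species exceeds
`max(D_intra)`.

**Trees.** Saitou–Nei neighbour joining with deterministic tie-breaks and
clamped negative branches; nonparametric bootstrap over alignment columns
(default 1000 replicates) with bipartition-frequency supports on the
full-data tree; species monophyly testing in unrooted terms, also applicable
to imported Newick trees (e.g. externally estimated ML topologies).

**Combinations.** All locus subsets of arity 2–5 re-analysed over the
specimens shared by every member locus, on the concatenated alignment.

A simulator with known truth (`simulate_dataset()`, K2P substitution process
along a species tree, star-shaped intraspecific variation, per-locus
amplification dropout) makes the entire pipeline testable offline;
`study_fixture()` reproduces a realistic study design of 66 specimens, 12
grass species and 6 loci with published PCR success rates as dropout
probabilities.

## Worked example

```r
library(barcodeEval)

sim <- simulate_dataset(study_fixture(seed = 42))   # 66 specimens, 6 loci
res <- barcode_eval(sim$datasets, reps = 100, arities = 2, seed = 42)
res
#> Barcode locus evaluation
#>   loci: atpF, ETS, ITS, matK, ndhK, psbE
#>   model: k2p, bootstrap reps: 100, seed: 42
#>   loci with a clear barcode gap: ITS
#>   combinations analysed: 15

summary(res)[, c("locus", "n_sequences", "aligned_length",
                 "informative_sites", "locus_gap", "n_supported")]
#>   locus n_sequences aligned_length informative_sites locus_gap n_supported
#> 1  atpF          55            457               193     FALSE          11
#> 2   ETS          25            491               108     FALSE           3
#> 3   ITS          23            687               104      TRUE           3
#> 4  matK          49            838               306     FALSE          10
#> 5  ndhK          47            356               104     FALSE           6
#> 6  psbE          30            687               171     FALSE           4
```

Per locus: how many specimens amplified, the alignment length,
parsimony-informative sites, whether intraspecific and nearest-neighbour
distance ranges are disjoint (`locus_gap`), and how many species are
monophyletic with bootstrap support above 70%. Here the *atpF* analogue
amplifies nearly everything and confirms 11 of 12 species; the deliberately
close *Nassella* species pair (0.5% divergence) is what it fails on:

```r
head(res$loci$ETS$gap[, c("species", "n_specimens", "d_intra",
                          "nearest_species", "d_nn", "gap_present")], 4)
#>                  species n_specimens d_intra     nearest_species   d_nn gap_present
#> 1 Austrostipa densiflora           2   0.204 Nassella trichotoma  5.989        TRUE
#> 2         Chloris gayana           2   0.000   Hyparrhenia hirta 11.718        TRUE
#> 3      Hyparrhenia hirta           3   0.614      Chloris gayana 11.718        TRUE
#> 4      Nassella neesiana          10   1.025 Nassella trichotoma  0.615       FALSE
```

Distances are percentages; `d_intra` is `N/A` for singleton species.
`plot(res, "ETS")` draws the `D_intra` vs `D_NN` scatter with the identity
line; `run_all(run_config(..., out_dir = "out"))` writes the full report
bundle (TSV tables, Newick trees with supports, scatter plots, a JSON
summary and a log). A thin command-line front end is installed at
`inst/cli/barcode-eval.R` (`run -c config.yaml`, `simulate`).

The package also ships a reference table of published per-species
`D_intra`/`D_NN` values for six grass barcoding loci (`gap_reference()`),
useful for exercising the gap logic without sequence data.

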