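---
title: "Recognising nucleotide cyclase-like proteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising nucleotide cyclase-like proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclascan)
library(dplyr)
```

## The problem

Class III nucleotide cyclases synthesise cAMP and cGMP, second messengers
that bacteria use throughout their signalling networks. The family is
recognisable across billions of years of divergence not by overall
sequence identity — remote homologues can sit below 25 % — but by a
handful of function-conferring residues presented on a conserved
βααββαβ fold:

* **MB**: two metal-binding aspartates that coordinate the divalent
  cations required for catalysis;
* **SS**: a substrate-specifying residue pair contacting the purine base.
  Lys–Glu at these positions is the adenylyl-type configuration; when
  glutamate replaces the lysine (Glu–Lys or Glu–Arg) the protein is a
  guanylyl cyclase candidate;
* **TS**: transition-state stabilising residues (canonically Asn/Arg);
  many established cyclases lack the asparagine equivalent, which is
  associated with relaxed ATP/GTP discrimination.

`cyclascan` turns this residue-level reasoning into a reproducible
pipeline: given an alignment of candidate proteins with an established
cyclase as reference and the reference's catalytic residue numbers, it
reads the candidates' residues at the anchored positions, applies the
substrate-specificity rule, and supports the call with conservation
scores, motif and hydropathy screens, divergence analysis and
gene-neighborhood evidence.

## Conservation scoring

`conservation_scores()` summarises each alignment column on a 0–9 scale.
The scale has two fixed interpretation points: 9 means strict
conservation (a gap-free column with a single residue type), and 6–8
means a well-conserved column whose residues stay within one
physicochemical class. The formula between those points is this
package's own choice and is deliberately simple. With `n` rows, `g` gaps
in the column, and `f` the largest fraction of rows in a single
physicochemical class,

```
score = 9                                if g = 0 and one residue type
score = min(8, floor(9 f (1 - g/n) + 0.5))  otherwise
```

The residue classes are a standard Taylor-style grouping:
`{A,V,L,I,M,C}`, `{F,W,Y,H}`, `{S,T,N,Q}`, `{D,E}`, `{K,R}`, `{G}`,
`{P}`, `{X}`. Gaps count toward no class, so gap-rich columns are pulled
down both through `f` and through the `(1 - g/n)` factor. Consensus ties
break alphabetically, so output is deterministic. Rendering pipelines
that produce such scores rarely publish their exact formula; only the
two fixed points above should be treated as comparable across tools, and
the documentation says so rather than pretending to reverse-engineer any
particular renderer.

```{r conservation}
conservation_scores(tibble::tibble(id = c("a", "b", "c", "d"),
                                   seq = c("DKD", "EKD", "DKW", "EK-")))
```

## Position anchoring and coordinates

Catalytic positions are supplied as an `anchor_config()`: the reference
sequence id plus 1-based *ungapped* residue numbers for MB1, MB2, SS1,
SS2, TS1 and optionally TS2. TS2 exists because guanylyl-type references
are conveniently described by two stabilising positions (e.g. His and
Arg) while adenylyl-type references need only the arginine; whether the
two frames' TS positions are homologous is not assumed anywhere — TS
residues are reported as evidence and never affect the label.
`map_reference_position()` projects a residue number to its alignment
column; everything user-facing is 1-based, matching R convention.
Reference anchor numbers are user input by design: they depend on which
structure the user aligned against, and typical sources are the
annotated active site of a solved cyclase structure.

## The classification rule

`classify_profile()` is a pure function of the MB/SS/TS residues:

* SS = (K, E) → `AC/GC` (adenylyl-type; the missing asparagine
  equivalent in this family argues for dual ATP/GTP capability, so the
  dual label is emitted rather than plain AC);
* SS = (E, K) or (E, R) → `GC`;
* anything else → `unclassified`. The rule set is closed-world: patterns
  outside the curated vocabulary are not guessed at.
* MB with no aspartate → forced `unclassified` (metal coordination is
  indispensable); exactly one aspartate keeps the SS-rule label but sets
  `mb_ambiguous`, mirroring how curators flag such entries rather than
  discard them.

Two screens support the calls on unaligned sequences.
`scan_ggdef()` reports every occurrence of the Gly-Gly-Asp-Glu-Phe
pentapeptide diagnostic of diguanylate cyclases; candidate cyclases of
the kind this package targets should lack it. `hydropathy_tm_screen()`
is a Kyte–Doolittle sliding-window screen (window 19 residues, mean
hydropathy threshold 1.6 — common conventions for a transmembrane-helix
screen); an empty result is consistent with a cytosolic protein. It is
explicitly a hydropathy screen, not a topology predictor: it trades the
sophistication of HMM-based predictors for transparency and zero
external dependencies, which is sufficient for its role here as a
negative filter.

## Redundancy reduction

`dedup_exact()` collapses identical sequences (representative = smallest
id). `greedy_cluster()` is a reproducible greedy centroid clusterer:
records in decreasing length order join the first cluster whose
representative shares at least the threshold identity.
`global_identity()` uses Needleman–Wunsch with match +1, mismatch 0,
linear gap −1, and defines identity as matches divided by alignment
length — a conservative, symmetric convention. Classic clustering tools
differ in their denominators and coverage rules; because published
methods sections rarely pin those details, the convention here is chosen
for symmetry and stated openly rather than matched to any one tool.

## Divergence analysis

`pdistance_matrix()` computes p-distances with pairwise deletion by
default (complete deletion by flag) and an optional Poisson correction
`d = -ln(1 - p)`; the default correction is Poisson, a standard choice
for protein distances when no substitution model is specified. A pair
with no shared non-gap columns, or p = 1 under Poisson, is an error
naming the pair — silent NaNs are never produced.

`nj_tree()` implements Saitou–Nei neighbor joining with the
Studier–Keppler Q criterion. Two choices make it bit-reproducible:
ties in the Q minimisation break by the smallest (i, j) pair in current
node order, and negative branch-length estimates are clamped to zero
without redistribution (simple, and honest about the fact that negative
lengths are estimation artefacts). For two taxa the cherry spans the
pairwise distance; for three, the closed-form star lengths
`v_i = (d_ij + d_ik - d_jk)/2` are used. On additive matrices NJ
provably recovers the generating topology; the test suite exercises this
across random trees of 4–8 taxa against an independent implementation.

`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the NJ tree per replicate, scores each internal edge of the
full-data tree by the percentage of replicates containing its
bipartition, and collapses edges below the cutoff (default 50 %) into
polytomies; supports are reported as integers on the internal nodes.
Replicates with undefined distances are discarded and counted — more
than half discarded is an error. One degenerate case is handled
explicitly: an alignment of identical sequences has no resolvable
structure, yet deterministic tie-breaking would reproduce the same
arbitrary topology in every replicate and thus fake full support. The
package returns a single star polytomy with no supports instead.

`separation_statistic()` quantifies a two-cluster structure as
S = mean between-block distance / mean within-block distance, with an
infinity sentinel when the within mean is zero, and (given a tree)
verdicts whether the partition is a bipartition of that tree. Under
exchangeable distances S ≈ 1; planted-clade simulations in the test
suite require S > 2 and monophyly.

## Rosetta-stone neighborhood analysis

Functionally coupled genes tend to sit near each other in prokaryotic
genomes, and two separately encoded proteins are likely to interact if
their homologues occur fused in some genome (the Rosetta-stone
argument). `conserved_neighbor_pairs()` finds, for a query orthogroup,
the neighbor orthogroups recurring near it across genomes;
`cooccurring_domains()` builds the set of domains that share an
architecture with the cyclase domain; `rosetta_associations()` emits one
association per supporting genome and per partner domain inside that
set, with function categories looked up from a user-supplied map.

Geometry and thresholds:

* neighborhoods are measured in gene-index steps, not base pairs — gene
  tables carry order, not coordinates — with a default window of 10
  genes per side, which covers the offsets seen in curated associations
  (up to ~7 locus-tag steps) with margin;
* `min_genomes = 2` is the weakest reading of "conserved across multiple
  genomes"; it is a knob because no sharper criterion is defensible
  without a genome-relatedness model;
* contigs are linear (no circular wraparound; irrelevant at window
  scale), strand is ignored, and orthogroup labels are inputs — the
  package does not infer orthology from sequence.

## Synthetic data and what it shows

The `simulate_*()` generators produce data with exactly the statistical
structure the analysis assumes, plus a ground-truth object, so tests can
score recovery instead of eyeballing plots. All are pure functions of
(parameters, seed); seeds are mandatory arguments, never global state.

* `simulate_family()` plants canonical MB/SS/TS residues in a reference
  and mutates queries i.i.d. (non-key sites at `mut_rate`, key sites at
  `key_mut_rate`, uniformly to another residue). Defaults: length 250
  (typical for the single-domain proteins this emulates), `mut_rate`
  0.2 — within-family divergence large enough to be non-trivial while
  leaving family signal intact. The truth table records every key-site
  residue, so the expected mislabel set is computable exactly: a query
  loses its planted label iff an SS site mutated or both aspartates were
  lost.
* `simulate_two_clades()` fixes `n_fixed_diffs` inter-clade differences
  (30 by default in tests, i.e. 12 % of a 250-residue alignment) and
  adds within-clade noise at `intra_rate` 0.01. The acceptance-scale
  checks use 10 + 10 leaves and 100 bootstrap replicates across 10
  seeds, sizes at which the planted split must reach 100 % support.
* `evolve_on_tree()` runs a uniform substitution process (substitution
  probability `1 - exp(-rate * t)` per branch) over an `ape` tree.
* `simulate_genomes()` plants one query gene, one partner at a fixed
  offset carrying the planted domain, and decoy genes whose orthogroups
  never recur across genomes — so conservation filtering must recover
  the partner with zero false discoveries.
* `simulate_redundant_set()` plants exact duplicates (defaults 53 unique
  + 31 duplicates = 84 records) for deduplication tests.

Limitations worth keeping in mind: substitutions are uniform over the 20
residues (no WAG/LG-style rate matrix), there are no indels (gap
handling is exercised by small hand-built alignments instead, keeping
the mapping tests interpretable), and genomes have no rearrangement
process. Passing on these generators demonstrates correctness of the
algorithms under their stated assumptions; it does not demonstrate
robustness to alignment error or compositional bias in real data.

## The packaged reference annotation

`load_key_residue_table()` ships a curated set of 53 uncharacterised
bacterial proteins (22 Actinobacteria, 23 Bacteroidetes, 8
Proteobacteria) with their key residues and predicted class, and
`load_association_table()` a companion set of 20 functional
associations over 12 of those proteins and 5 partner domains. Fixture
files are pinned by checksum; `classify_reference_table()` re-derives
every label from the residues and reports (never edits) mismatches.
The key-residue cells are stored pre-parsed into MB/SS/TS fields
because run-together table typography is ambiguous; the three-category
split follows the standard MB/SS/TS scheme. One curiosity is preserved
as printed rather than resolved: both single-aspartate entries are
flagged exactly as curated even though related gene records in the
wider literature make the second flag debatable.

```{r fixture}
rep <- classify_reference_table()
glance(rep)
rep$crosstab
```

## Pipeline and reproducibility

`run_pipeline()` chains the stages (conserve → classify → cluster →
tree → neighbors) from a config list or YAML file, validates the whole
configuration before running anything, writes one TSV/Newick per stage
plus a JSON run log (package version, seed, parameters), and on stage
failure removes partial outputs and names the failing stage. Identical
configs and seeds give identical output bytes.

Problem sizes used by the test suite were chosen to exercise each
property at the smallest scale where it is meaningful: NJ consistency on
50 random trees for each of 4–8 taxa, bootstrap recovery on 20-taxa
alignments of 250 columns with 100 replicates over 10 seeds,
neighborhood recovery on 3 genomes × 22 genes over 10 seeds, and a
1000-sequence motif-scan cross-check against a brute-force oracle.

## Known limitations

* The conservation formula matches the 0–9 scale's fixed points but is
  not a reimplementation of any specific renderer's score.
* The hydropathy screen is not TMHMM/SignalP; borderline membrane
  topology should be re-checked with dedicated predictors.
* Greedy identity clustering approximates, but does not replicate,
  legacy BLAST-based clustering; coverage thresholds are not modelled.
* NJ with Poisson-corrected p-distances is a deliberately simple
  divergence model; no model selection, ML or Bayesian inference is
  attempted, so trees are for cluster structure, not dated phylogenies.
* Rosetta-stone calls are only as good as the orthogroup labels and
  domain architectures supplied in the gene tables.
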