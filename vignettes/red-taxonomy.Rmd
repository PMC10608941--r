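---
title: "Rank normalization with relative evolutionary divergence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank normalization with relative evolutionary divergence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`redtax` turns a collection of genomes and metagenome-assembled genomes
(MAGs) into rank-normalized taxonomy: quality gating, ANI dereplication into
species clusters, a concatenated marker supermatrix, a rooted tree, and
relative-evolutionary-divergence (RED) intervals that assign ranks to
lineages. This vignette explains each model, the parameters that matter, the
synthetic-data generator the tests rely on, and the design choices made
where the design was genuinely open.

## The RED model

On a rooted tree with non-negative branch lengths, RED interpolates node
depth between the root (0) and the extant leaves (1). In preorder, a node
`n` with parent RED `P`, branch `a` to its parent, and mean distance `b`
from `n` to its descendant leaves receives

$$\mathrm{RED}(n) = P + \frac{a}{a+b}\,(1 - P).$$

Three consequences shape everything downstream:

* every leaf gets exactly 1 (its `b` is 0), the root exactly 0;
* the value is invariant under global rescaling of branch lengths, so trees
  inferred under different rate calibrations remain comparable;
* RED is monotone along every root-to-leaf path, which is what lets ranks
  nest.

Numerical conventions: a node reached through a zero-length branch whose
subtree also has zero depth (`a + b = 0`) inherits its parent's RED — the
continuity limit as `a` goes to 0. Zero-length internal branches are kept,
not collapsed. Only a single rooting is used (the outgroup rooting of the
workflow); averaging RED over alternative rootings, as some reference
implementations do, is deliberately not implemented, matching a
single-outgroup analysis.

The implementation is a two-sweep dynamic program (postorder for mean leaf
distances, preorder for the recursion). The test suite checks it against an
independent oracle that recomputes `b` from the full node-to-node distance
matrix, over all rooted topologies with 4–6 leaves on a branch-length grid
spanning two orders of magnitude, at a tolerance of 1e-12.

## Rank intervals and reclassification

A `rank_model` is the per-rank median RED of rank-labeled reference nodes
plus an interval half-width `w`. The default `w = 0.1` applies one width to
all ranks, following the convention in which a phylum is indicated by an
interval of roughly ±0.1 around the reference median; whether narrower
per-rank widths would be preferable is left to the user, and `w` is an
explicit parameter. Assignment tests a node's RED against every interval
`[median − w, median + w]`; among containing ranks the nearest median wins,
ties resolve to the shallower rank, and a value inside no interval falls
back to the overall nearest median with an `in_interval = FALSE` flag.
Reclassification compares labeled against assigned ranks and proposes
demotions (assigned deeper) or promotions (assigned shallower). The rank
model is always fitted on clean reference labels; a questioned lineage is
evaluated against that calibration, never allowed to pollute it.

## Quality gating

All percentages live on the 0–100 scale. Contamination is paralog-corrected,
`c_pc = c − c(h/100)`, where strain heterogeneity `h` measures how much of
the contamination signal is same-species strain variation rather than
foreign DNA. Completeness blends two estimators, `0.8·primary +
0.2·secondary`, weighting the marker-set estimator higher because the
secondary (reference-tree based) estimator is the noisier of the two. A
genome must keep both raw contamination estimates strictly below 10%,
survive the pre-filter (at least 50,000 bp, contamination at most 20%,
completeness at least 25%), and reach the medium draft tier (completeness
strictly above 50%, corrected contamination strictly below 10%; the high
tier needs >90% and <5%). Boundary semantics follow the printed inequality
directions exactly — a genome at completeness 50.0 is *not* medium quality,
while contamination exactly 20.0 survives the pre-filter — because strict
boundaries are auditable.

## Sketch ANI and two-stage dereplication

Genomes are reduced to bottom sketches: canonical (strand-minimal) k-mers
are 2-bit encoded (`k = 21`, exact in doubles up to `k = 26`), scrambled
with a 31-bit universal hash so the bottom of the hash order is not biased
toward low-complexity k-mers, and the smallest `sketch_size` hashes kept.
The Jaccard index `J` estimated over the bottom of the union sketch relates
to per-site identity `a` through the k-mer survival model
`w = 2J/(1+J) = a^k`, so the estimator inverts exactly:

$$\mathrm{ANI} = 100\,\left(\frac{2J}{1+J}\right)^{1/k}.$$

The familiar log form `d = −(1/k)\ln(2J/(1+J))` is the first-order expansion
of this inversion; it understates ANI by about half a point at the 90%
species boundary, which matters when calibration to within one point is the
goal, so the exact form is used. With the default `sketch_size = 1000` the
sampling standard deviation at ANI 90 is roughly half a point; calibration
tests and the acceptance script therefore sketch at 4000, trading a few
milliseconds for a ~0.25-point standard deviation. Overlap — the containment
of the smaller sketch in the larger — stands in for the aligned-fraction
gate of alignment-based dereplication tools.

Clustering is greedy and quality-ordered (score: completeness −
5·contamination, ties by assembly size then id): the best genome seeds a
cluster, later genomes join the first compatible centroid. A primary pass
groups at the primary ANI threshold; a secondary pass inside each primary
group applies the secondary threshold *and* the overlap gate. Two presets
mirror the two uses of dereplication: `"coarse"` (90/99, 50% overlap)
removes redundant assemblies early, `"species"` (80/95, 10% overlap) forms
species clusters at the conventional 95% boundary. The overlap gate is
applied only in the secondary pass — the primary pass is a coarse grouping
for which no overlap rule is specified — and the representative score is the
common dereplication heuristic, stated explicitly so it is auditable.
Novelty categories collapse the fine-grained provenance taxonomy of larger
surveys to four auditable classes (all public, all novel, novel
representative/majority, public representative).

## Markers, supermatrix, and the rpoB guard

Hits are accepted at the per-model cutoff `(TC + NC)/2`, the midpoint of the
trusted and noise bit-score cutoffs bundled with profile HMMs, keeping the
best hit per genome and marker. Markers modeled in fragments (the rpoC case,
where two extra models cover lineages with a split gene) are concatenated in
declared order with absent parts gap-filled, so the merged marker has fixed
width. Marker/genome selection iterates to a fixed point: markers present in
fewer than 90% of genomes are dropped, then genomes carrying fewer than 50%
of the surviving markers, until stable — an explicit stand-in for the
unpublished reduction rule that produced the original 19- and 50-gene sets,
and the main knob to adjust when porting to real hit tables.

Because the simulator evolves markers without indels, alignment is the
identity in tests; for unequal lengths a star alignment (global pairwise to
the longest sequence, match +1 / mismatch −1 / gap −2, gaps projected
through the center) keeps the pipeline self-contained. Production users
should substitute a real aligner/trimmer upstream and feed equal-length
FASTA in. Columns with more than 50% gaps are trimmed with an index map, and
concatenation records half-open, 0-based column intervals per marker, with
missing markers as all-gap blocks rather than dropped rows. Supermatrices
whose columns derive more than 20% (strictly) from rpoB are flagged: trees
dominated by that single gene have shown clades unsupported by broader data,
so the check guards marker-set composition.

## Tree building and decoration

Distances are computed gap-aware from the supermatrix (`p` = mismatches over
shared non-gap columns; Poisson correction `−ln(1−p)` with `p` capped at
0.95), and the tree is standard neighbor joining with negative branch
lengths clamped to zero — a deterministic, dependency-light stand-in for
likelihood inference that is adequate for RED property testing; parity with
a production ML tree is not a goal. Rooting requires the outgroup to be
separable by a single edge and places the root at that edge's midpoint,
which is this package's explicit choice where the underlying convention is
unstated. Decoration labels each named taxon's MRCA and flags monophyly by
exact leaf-set comparison.

## Balanced taxon sampling

Taxa with `n ≤ 3` genomes are kept whole; larger taxa are reduced to
`3 + 0.2(n − 3)` genomes. The formula's rounding is not specified in its
source, so half-up rounding is used (103 → 23, 10 → 4.4 → 4); retained
genomes are the top-quality ones with seeded uniform tie-breaking, both
stated here for determinism. The grouping rank is a parameter
(`downsample_rank`, default genus) because "per overlying taxon" is
ambiguous between species- and genus-level grouping in the source workflow.

## The synthetic generator

`sim_config()` fixes the study conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `n_taxa` / `n_outgroup` | 20 / 4 | ingroup and outgroup species |
| `genomes_per_species` | 3 | MAGs per ingroup species |
| `n_markers` × `marker_len` | 20 × 120 | supermatrix of 2400 columns |
| `genome_len` | 100 kb | smallest size at which sketch ANI is well calibrated |
| `subst_rate_per_branch` | 0.5 | marker substitutions per site per unit branch |
| `within/between_divergence` | 0.004 / 0.065 | per-site divergence from species reference / root |
| `rank_depths` | 0.15–0.9 | RED depths at which ranks are planted |

Branch lengths are drawn uniformly on [0.05, 1]; the floor keeps every
internal edge resolvable so that topology-recovery properties test the
method rather than degenerate simulations. Species references diverge
~0.065 from a common root (pairwise ~0.124, true ANI ~87.6, safely below
the 90% primary threshold), members diverge ~0.004 from their reference
(pairwise ~0.008, true ANI ~99.2, safely above the 95% secondary
threshold) — a two-point-plus margin on both sides of the clustering
thresholds. Mutations hit an exact count of distinct sites, so true ANI is
known exactly and serves as the estimator's oracle. Rank labels are planted
on the RED scale itself (each ingroup internal node takes the rank whose
configured depth is nearest the node's RED), which is what "planting a rank
at a relative depth" means in a RED-based framework. MAG degradation
fragments genomes into contigs uniform on [1500, 50000] bp (mirroring a
1500 bp assembly contig floor), keeps a random subset matching the target
completeness within one contig, and appends contigs from a different
species as contamination. Default quality mixtures (85% of MAGs at
completeness 0.7–1.0, 15% at 0.3–0.5; 90% at contamination 0–4%, 10% at
12–25%) make the filtering cascade non-trivial: some genomes fail each
gate. The synthetic QC reports carry the injected truth on both estimators;
emulating estimator error is out of scope, so gate decisions on synthetic
data equal decisions computed from truth by construction.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: gene content and genome architecture (markers are
abstract fixed-length proteins, genomes are i.i.d. nucleotides without
repeats or skew), indels and alignment uncertainty, estimator noise in QC
tools, rate heterogeneity across sites and lineages, horizontal transfer,
and chimeric binning beyond simple foreign-contig contamination. Repetitive
or low-complexity real genomes will give noisier sketch ANI than the i.i.d.
simulations suggest.

## Problem sizes and determinism

The shipped tests and the acceptance script run at deliberately desk-scale
sizes: all 4–6-leaf topologies (with sampled grid branch lengths) for the
RED oracle, ten 200-leaf trees for rank recovery, 100 kb genome pairs at
mutation rates 0.01–0.10 for ANI calibration, a 5-species × 4-genome planted
fixture for cluster recovery, and the default 64-MAG pipeline for end-to-end
determinism. All randomness flows from one integer seed through a named
seed-derivation chain; no function touches global RNG state without
restoring it, which is what makes rerun reports byte-identical.

## Known limitations

* NJ on ~20-leaf representative trees re-estimates branch lengths with
  enough distortion that a handful of borderline planted nodes can cross
  rank-interval boundaries; end-to-end runs may therefore contain a few
  proposals beyond any deliberately planted one. Rank-interval logic should
  be judged on the generating-tree tests, the end-to-end run on its
  determinism and cascade accounting.
* Sketch ANI degrades for very incomplete genomes (shared k-mer content
  falls with the product of completenesses); the pipeline mitigates this by
  gating quality before dereplication, as real workflows do.
* The star aligner is for completeness of the interface, not a substitute
  for production multiple alignment.
* The 129→19/50 marker-reduction rule and the 11-way novelty taxonomy of
  the original survey are unpublished; the fixed-point filter and the
  4-way categories here are explicit, documented stand-ins.
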