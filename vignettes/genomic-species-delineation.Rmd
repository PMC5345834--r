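---
title: "Delineating genomic species and subspecies from whole-genome distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating genomic species and subspecies from whole-genome distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genospec)
```

## The problem

Prokaryotic species are operationally defined by genome relatedness: strains
whose DNA:DNA hybridization is at least 70% — today estimated *in silico* on
the same percentage scale (dDDH) — or whose average nucleotide identity (ANI)
is above roughly 94–96% belong to one species; a 79% dDDH cutoff delineates
subspecies. Collections of tens of isolates from a genus (here, the
motivating case is sulfur-oxidizing haloalkaliphiles from soda lakes) must be
partitioned into described and novel genomic species using these thresholds,
and the decision procedure has more moving parts than a plain clustering:

1. **Type-radius affiliation.** Only distance to a *type strain* is
   nomenclaturally meaningful. Every strain within, say, the 70% dDDH radius
   of a described type is attributed to that species.
2. **De-novo clustering of the remainder.** Unaffiliated strains are
   clustered by threshold linkage: strains are *linked* when their pairwise
   distance is at most `T`, and two clusters merge only when the fraction of
   linked inter-cluster pairs reaches the linkage fraction `F` (`F = 0`:
   single linkage, one link suffices; `F = 1`: complete linkage, all pairs
   must be links). All runs here use `F = 0.5`.
3. **Ambiguity scanning.** Each member of a novel cluster is treated in turn
   as a putative type (PT); strains that then fall inside two or more type
   radii are *ambiguities* — they make the species assignment
   threshold-dependent and are reported, not silently resolved.

The package implements this procedure end to end, together with the pairwise
measures it consumes (fragment ANI, tetranucleotide signature correlation,
trimmed-HSP genome-BLAST distances), marker-gene identity statistics,
distance dendrograms with replicate-based support, a biogeographic
classifier, and a simulator that plants a known species/subspecies structure
so the whole pipeline can be validated without any external data.

## Pairwise measures

**Fragment ANI (`anib`, `anib_matrix`).** The query genome is cut into
consecutive 1020 bp fragments (terminal fragments kept from 100 bp); each
fragment is aligned to the reference by `blastn`; fragments are retained
when the best alignment reaches 30% identity over at least 70% of the
fragment; ANI is the mean identity of retained fragments. The 1020/30%/70%
retention rule is the convention of the widely used BLAST-ANI
implementations; all three values are arguments. Matrices are built from
both directions of every pair and symmetrized by arithmetic mean, because
fragment ANI is directional and published tables rarely state which
direction they report; asymmetries above 0.5 percentage points are treated
as data corruption rather than averaged away. For matrix construction the
default seeding is megablast (fast, reliable down to ≈85% identity, which
covers everything inside a genus); the single-pair `anib()` uses the
sensitive `blastn` seeding with the conventional +1/−1 match/mismatch,
5/2 gap costs and word size 11.

**Approximate alignment ANI (`anim_approx`).** A deliberately lightweight
stand-in for whole-genome-aligner ANI: maximal exact matches of ≥ 20 bp are
anchored via a k-mer index, anchors on one diagonal are chained gap-free,
and block identities are computed by direct base comparison. It is labelled
`approximate = TRUE` in every result and is *not* claimed to reproduce
MUMmer-based values; on simulated within-species pairs it tracks fragment
ANI within one percentage point (asserted in the tests).

**Tetranucleotide signature (`tetra_profile`, `tetra_correlation`).** Both
strands of every contig are counted; tetramer counts are converted to
z-scores against the maximal-order Markov expectation
`E(n1n2n3n4) = N(n1n2n3) N(n2n3n4) / N(n2n3)`, and two genomes are compared
by Pearson correlation of their 256 z-scores. Published species screens use
0.989 and 0.999; although an early description attached a percent sign to
these numbers, they are correlation coefficients and are treated as such.

**Genome-BLAST distance (`gbdp_distance`).** High-scoring segment pairs
between two genomes are collected, trimmed greedily by descending score so
no query position is covered twice, and summarized as
`d = 1 − Σ identities / Σ trimmed HSP length`. One hundred replicate
distances are obtained by resampling HSPs with replacement (the analogue of
bootstrapping entire genes) and drive pseudo-bootstrap branch support in
distance trees. The mapping `ddh_like = 100 (1 − d)` is a **surrogate**: the
calibrated regression of the reference web service is proprietary to that
service and is *not* reproduced here. The backend is pluggable — supply a
`calibration` function, or bypass computation entirely by reading a
published dDDH matrix with `read_labeled_matrix(..., kind = "dDDH")`, which
is the only mode in which published dDDH-scale thresholds (70/79%) are
numerically meaningful.

**Scale conversions.** Percent similarities convert to distances as
`(100 − s)/100` (so the 70% radius is distance 0.30 and 96% ANI is 0.04);
tetranucleotide correlations convert as `1 − r`.

## The clustering engine

`fraction_linkage_cluster()` starts from singletons and repeatedly performs
the admissible merge (link fraction `f ≥ F`, and `f > 0` so that `F = 0`
degenerates to connected components / single linkage) with maximal `f`,
breaking ties by smaller mean inter-cluster distance and then by the
lexicographically smallest pair of cluster label minima. The merge order of
the original threshold-linkage optimizer is not published; this greedy
max-`f` order with a total tie-break is this package's convention, chosen so
that results are reproducible bit for bit. The `F ∈ {0, 1}` endpoints are
verified against independent single-linkage (connected components) and
complete-linkage-property oracles on dozens of random matrices in the test
suite.

Other conventions that the source procedure leaves open, decided here once
and tested:

* Step-2 de-novo clustering covers **only** the unaffiliated strains;
  strains already inside a described type's radius do not participate in
  link fractions of novel clusters.
* The putative type retained for a novel cluster is a strain whose radius
  captures exactly its own cluster; if none exists, the medoid-like strain
  with maximal within-cluster minimum similarity (lowest label on ties).
* Ambiguities are counted as *strains* inside ≥ 2 radii of the described
  types plus retained putative types.
* Threshold comparisons are `≤` on distances (equivalently `≥` on
  similarities), matching the stated "smaller or equal" linkage rule.
* Subspecies clustering within a described species uses no type anchoring,
  and an undivided species contributes no subspecies: `nontrivial_count`
  counts sub-clusters of ≥ 2 strains inside species that actually split.

## The simulator and what passing tests mean

`simulate_species_complex()` evolves genomes down a fixed
root → species ancestor → subspecies ancestor → strain hierarchy under a
Kimura two-parameter substitution model (transition:transversion 2.0, no
indels). Per-branch rates are halves of band increments, so the *pairwise*
divergence of two strains matches the band of their most recent shared
level:

| level | default band (subst./site) | expected ANI |
|---|---|---|
| within subspecies | 0.005 | ≈ 99.5% |
| within species | 0.03 | ≈ 97% |
| between species | 0.10 | ≈ 90% |
| between genera | 0.25 | (not used by default) |

The defaults straddle the conventional boundaries — within-species pairs
land above 96% ANI, between-species pairs well below 94% — which is a design
requirement, not an empirical claim; the calibration (band 0.03 ↔ ANI ≈ 97%)
is asserted empirically in the tests because fragment filtering, not just
the substitution count, shapes ANI. The default complex is 6 species of
sizes 6/4/4/3/2/1 (20 genomes, 200 kb, 5 contigs each, G+C 0.63, half the
species "described" with a designated type strain); species with ≥ 4 strains
are split into two planted subspecies. These sizes keep a full 20-seed
recovery suite within a few minutes on one CPU while leaving every code path
(affiliation, de-novo clustering, putative types, subspecies, biogeography)
exercised.

The root genome is drawn from a random third-order Markov chain
(Dirichlet-distributed transition rows, concentration 1.5): this plants a
genome-wide oligonucleotide signature — tetramer usage not predictable from
trimer composition — without which tetranucleotide correlations of simulated
genomes would be pure noise, unlike real genomes. With the signature,
within-species pairs correlate above 0.999 and independent genomes near 0,
reproducing the qualitative geometry of real data.

Because the surrogate ddh-like scale is not the calibrated hybridization
scale, published 70%/79% cutoffs do not transfer numerically to simulated
runs. For recovery tests the *equivalent* cutoff is derived from the planted
bands themselves (`equivalent_cutoff()`: the similarity halfway between the
two bands the boundary separates — e.g. 98.25% for the subspecies boundary
under default bands). This is a property of the simulation design, fixed
before any test outcome and never tuned.

What the simulator does **not** model: gene content differences,
rearrangements, horizontal transfer and recombination (in real populations
often the dominant diversifier), indels, sequencing error, and assembly
artifacts. Passing recovery tests therefore demonstrates the correctness of
the inference machinery under the stated divergence geometry — not that real
collections will be as clean; real data show exactly the threshold-dependent
ambiguities the procedure is designed to surface.

## Marker genes

`pairwise_identity()` implements both identity conventions found in
practice through one `gap_policy` switch: `"gaps-are-differences"` (the
number-of-differences convention; used for the multilocus screen) and
`"exclude-pairwise"`. `k2p_distance()` evaluates
`d = −½ ln((1 − 2P − Q)√(1 − 2Q))` and errors on saturation
(`1 − 2P − Q ≤ 0` or `1 − 2Q ≤ 0`); whole-alignment summaries report
saturated pairs as missing with a warning instead of aborting. Columns
containing `N` are not counted as polymorphic (ambiguity codes are not
states). The eight housekeeping loci are always concatenated in the fixed
order clpA, atpD, gyrB, rpoH, secF, dnaJ, rpoD, rpoS regardless of supply
order; with the published alignment lengths the concatenation is 12,283 bp.
The multilocus species screen calls > 98.13% same-species and < 97.77%
different-species, with a grey zone between; the 16S genus-separation screen
tests inter-group identities against 94.8% ± 0.25.

`simulate_marker_alignments()` evolves gap-free loci on the same planted
hierarchy with per-locus rate multipliers (16S at 0.15× the housekeeping
rate, mirroring the strong conservation of the ribosomal marker relative to
multilocus data in real genera).

## Trees and biogeography

UPGMA dendrograms come from average-linkage `hclust` (labels sorted first so
equal-height merges are deterministic); ultrametricity is asserted in tests.
Phylogenomic trees from GBDP distance matrices use standard neighbor
joining — the balanced minimum-evolution + tree-rearrangement program used in
the motivating study is replaced by NJ because NJ is fully specified and
deterministic, and clade-level checks (planted species monophyly, outgroup
rooting) do not require branch-swapping; the substitution is recorded in
the package documentation rather than hidden. `replicate_support()` attaches
the percentage of replicate trees containing each reference bipartition.

`classify_distribution()` reduces isolation regions to macro-regions
(default map: Central Asian steppe regions, East/North Africa, North
America, engineered systems — user-overridable) and calls a cluster
*candidate endemic* (one macro-region) or *candidate disjunct* (two or
more); clusters with fewer than four located strains keep their provisional
verdict flagged `confident = FALSE`, since nothing robust can be said about
dispersion from two or three isolates. Region granularity is a convention:
with a different map the same data can legitimately yield different
verdicts, which is why the map is an argument and is echoed in pipeline
output.

## Numerical and degenerate-input choices

* Matrix symmetrization tolerates asymmetry up to 0.5 percentage points
  (0.005 for correlations/distances), then errors.
* Diagonals are forced to the declared scale (100 / 1 / 0) after reading.
* Zero-variance tetranucleotide profiles (e.g. homopolymers) error on
  correlation rather than returning `NaN`; zero-variance *cells* get z = 0.
* Genome pairs with no BLAST HSPs get distance 1 (similarity 0) with a
  warning; pairs with no retained ANI fragments error with a `no-homology`
  message in single-pair mode and become similarity 0 with a warning in
  matrix mode.
* All stochastic steps (simulation, HSP bootstrap) take explicit seeds and
  restore the caller's RNG state; identical inputs give byte-identical
  outputs, asserted in tests.

## Validation layout

The test suite validates every operation against independent oracles:
sliding-window tetramer counting, per-site transition/transversion
classification plus an established K2P implementation, brute-force column
counting for identities, connected-components and complete-linkage oracles
for the clustering endpoints, pair-counting for the adjusted Rand index,
hand-computed UPGMA merges and additive-matrix NJ recovery, and a 20-seed
planted-partition recovery suite at the default bands (20 genomes × 200 kb
per seed) requiring exact species and subspecies recovery (adjusted Rand
index 1) on at least 95% of seeds. `scripts/acceptance.R` re-runs the full
pipeline from scratch at a caller-supplied seed and writes the headline
quantities as JSON.

Published headline numbers that depend on the original study's
supplementary similarity matrices (the 25-species/0-ambiguity partition, the
24/42/15 ambiguity counts, the 98.13/97.77 multilocus screen bounds) are
reproduced by the same functions *only when those matrices are supplied*;
the tests that assert them look for CSV exports under
`inst/extdata/real/` and fail with a pointer when the export is absent, by
design — they are statements about external data, not about code that can be
validated synthetically.
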