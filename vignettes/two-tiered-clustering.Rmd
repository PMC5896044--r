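---
title: "Two-tiered drug clustering: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tiered drug clustering: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttclust)
```

## The problem and the model

Drug repositioning asks which existing drugs might serve therapeutic
purposes beyond their current classification. A drug is characterized by
several heterogeneous binary profiles — chemical fingerprints, disease
indications, target genes and proteins, reported side effects — and drugs
with similar profiles plausibly share therapeutic behavior. No single
profile is reliable on its own: each view is noisy and incomplete, and the
views disagree about which drugs are similar.

`ttclust` implements a two-tiered unsupervised integration of such views:

1. **Tier 1.** Each binary drug × feature view is clustered independently
   with a Growing Self-Organizing Map (GSOM), giving one homogeneous
   clustering per view.
2. **Integration.** Each Tier-1 clustering is converted into a binary
   drug–drug relation (DDR) matrix — entry 1 iff two drugs share a cluster
   — and the per-view DDR matrices are averaged with equal weights. The
   averaged matrix is a consensus (co-association) similarity: an entry of
   `3/4` means the pair co-clustered in three of four views, an entry of
   `0` means the pair never co-clustered.
3. **Tier 2.** The averaged similarity is clustered again, either as a
   weighted graph (Markov Clustering, MCODE, ClusterONE) or as vector data
   (a second GSOM on the matrix rows).
4. **Labeling and inference.** Each Tier-2 cluster is labeled with its
   majority second-level ATC therapeutic class, with confidence
   `n_majority / n_total`. Cluster members that do not carry the majority
   class — including entirely unclassified drugs — become repositioning
   candidates at that confidence. Proposals re-identified by at least two
   algorithms, or by two different clusters, are reported as consistent
   candidates.

Two simpler integration strategies are provided as baselines because they
are what the two-tier scheme should be judged against: `concat_hy`
concatenates all views into one wide binary profile before clustering, and
`avg_sim_hz` averages per-view pairwise Jaccard similarities into a single
dense matrix. The structural weakness of `avg_sim_hz` is that Jaccard
similarities are almost never exactly zero, so the integrated matrix is a
complete graph; co-membership averaging, by contrast, produces exact zeros
and therefore a sparse graph that graph clustering can cut. The package
keeps that contrast observable: `graph_from_ddr()` refuses a zero edge
threshold, and a Tier-2 run that collapses to a single cluster records a
warning on the fit.

## Evaluation

External agreement between a clustering and a reference classification is
measured information-theoretically on the contingency table of the two
partitions:

* `nmi_sqrt(U, V) = MI(U, V) / sqrt(H(U) H(V))` in [0, 1];
* `smi(U, V) = (MI - E[MI]) / sqrt(Var[MI])`, the number of null standard
  deviations the observed MI sits above chance, where the null fixes both
  sets of marginals and permutes labels.

`E[MI]` is the exact hypergeometric sum over feasible cell values.
`Var[MI]` is computed exactly as `E[MI^2] - E[MI]^2`, summing expected
products over ordered pairs of table cells: cells sharing a row (or
column) have a bivariate hypergeometric joint distribution, and disjoint
cells are handled by conditioning on the first row's draw. Both moments
are validated in the test suite against exhaustive enumeration of all
label permutations for tables up to n = 8, to 1e-9. Mutual information is
computed in natural logs; both indices are base-invariant so reported
values do not depend on that choice. Internal quality uses the Silhouette
`(b - a) / max(a, b)` with the convention that singleton items score 0.

Because the indices are defined on partitions, overlapping clusterings
(ClusterONE, fluffed MCODE) are reduced by assigning each drug to its
largest containing cluster (ties to the lexicographically smallest
cluster id), and drugs outside every cluster become singletons.
Multi-class drugs in the reference are resolved to a single class
uniformly at random under a recorded seed; unclassified drugs are
excluded from external evaluation, mirroring how a partially annotated
reference must be handled.

## GSOM: parameters and numerical choices

The GSOM starts from a 2 × 2 grid (`initial_nodes = 1` gives the
single-node emergent variant; the four-node start is the default because
it removes the degenerate first growth steps). Training presents samples
in a per-epoch shuffled order drawn from the run seed; the C++ core is
otherwise deterministic. The winner for each sample is the node with the
smallest (squared) Euclidean distance — ties go to the lexicographically
smallest grid coordinate — and the winner and its grid neighborhood move
toward the sample with a Gaussian neighborhood kernel. A Jaccard distance
mode is available for binary data.

Growth is controlled by the spread factor `SF` through the growth
threshold `GT = -D ln(SF)`: when a node's accumulated quantization error
exceeds `GT`, a boundary node spawns nodes at all free grid neighbors
(weights extrapolated across the winner and clamped to the data range)
while an interior node spreads its error to its neighbors. Two choices
here are deliberate and worth knowing about:

* **Error is accumulated per growing pass.** The accumulator is cleared
  at the start of every growing epoch, so `GT` is compared against one
  pass of quantization error and the final node count is governed by `SF`
  and the data, not by how long the map is trained. Without the reset,
  node counts grow linearly with the number of epochs and `SF` loses its
  meaning as a granularity control.
* **Defaults.** 50 growing + 50 smoothing epochs, learning rate 0.3
  decaying linearly (to 20% across the growing phase, then reduced by
  `smooth_lr_factor = 0.2`), neighborhood radius 3 shrinking to 1. These
  are conventional SOM schedules; all are arguments.

The pipeline's default spread factor (0.01 at both tiers) puts the map in
the coarse regime where the node count tracks the latent group count for
data of the scale the generator produces (about a hundred drugs in a
handful of groups). Granularity remains the user's main tuning decision,
exactly as it is for the original method: on a 417-drug, 60-group
configuration a spread factor around 0.6 reproduces maps of ~60 occupied
nodes. Node counts of any GSOM are implementation-specific — they depend
on the growth schedule — so agreement with other implementations should
be judged in regimes, not exact counts.

## Graph algorithms

All three Tier-2 graph algorithms are implemented here over `igraph`
structures:

* **MCL** builds a column-stochastic flow matrix with self-loops set to
  each vertex's maximum incident weight (1 for isolated vertices),
  then alternates expansion (`M^e`, default `e = 2`) and inflation
  (entrywise power `r > 1`, column renormalization) with pruning of
  entries below `1e-5`, until the largest change falls below `1e-6` or
  `max_iterations = 100` (non-convergence yields a warning and the last
  iterate). Clusters are the connected components of the symmetrized
  support of the limiting flow, which makes the output a partition.
  Inflation must exceed 1; toolbox-specific inflation scales below 1 used
  elsewhere have no canonical counterpart and are rejected.
* **MCODE** weights each vertex by `k · d`, the core number of the
  highest k-core of its closed neighborhood times that core's density,
  then grows complexes from seeds in decreasing weight order, admitting
  neighbors with weight at least `(1 - VWP)` times the seed weight.
  Vertices join at most one complex; haircut (on by default) iteratively
  removes members with fewer than two in-complex edges; fluff is off by
  default. MCODE ignores edge weights entirely, which is why a complete
  similarity graph always collapses to a single complex.
* **ClusterONE** grows groups greedily from seeds by the cohesiveness
  `f(S) = w_in / (w_in + w_bound + p|S|)` (penalty `p = 2`), accepting
  the best single addition or removal until no move improves `f`. Groups
  smaller than `min_size = 2` or with weighted density below
  `density_threshold = 0.6` are discarded, and groups with overlap score
  `|A ∩ B|² / (|A||B|)` at or above `overlap_merge_threshold = 0.8` are
  merged. The output may overlap and need not cover all drugs.

A practical note on greedy cohesiveness growth: on structures where two
dense groups share several vertices, the union often has higher
cohesiveness than either group, so the greedy pass returns the union —
overlap arises from seeds reaching different local optima (e.g. two
cliques joined through one bridge vertex), not from any pair of
intersecting dense sets.

## The synthetic generator

Real multi-view profile corpora require third-party database access, so
the package ships a generative model that preserves the features the
method exercises: `n_drugs` drugs in `k_groups` latent groups; per view, a
disjoint block of characteristic features per group carried by members
with probability `p_in = 0.9` against background `p_out = 0.05`;
independent per-view corruption flipping each cell with probability 0.02;
and an ATC-like reference derived from the groups with 16% of drugs given
a second (wrong) class and 3% left unclassified — the multi-class and
unclassified rates of the 417-drug corpus the method was developed on.
Defaults are five views of 60 features for 120 drugs in 6 groups.

Disjoint feature blocks make the planted structure identifiable and the
recovery tests sharp. What the generator does *not* emulate: the marginal
frequency spectrum of real chemical fingerprints, correlated side-effect
co-occurrence, view-specific drug coverage gaps, and group sizes as skewed
as real ATC classes. Passing the planted-recovery tests therefore shows
the pipeline is implemented correctly and integrates complementary noisy
views; it does not certify the corpus-level NMI/SMI figures, which depend
on the real profiles (shipped as a static benchmark table in
`tier_benchmarks()` for comparison and for the relative-gain arithmetic of
`relative_nmi_change()`).

## Problem sizes and costs

The validation suite runs the full pipeline on 120 drugs × 5 views × 60
features over five generator seeds (a few seconds per seed), which is the
scale at which recovery with NMI ≥ 0.95 for every Tier-2 algorithm is
asserted. Exact `Var[MI]` is an `O((rc)²)`-cell-pair computation; it is
instantaneous for tables up to a few hundred cells and is the default in
evaluation reports (`compute_smi = FALSE` switches it off where only NMI
is needed). The exhaustive permutation oracles in the tests are limited to
n ≤ 8, where enumeration (up to 8! relabelings) is still exact and fast.

## Known limitations

* GSOM node counts, and hence Tier-1 granularity, are schedule-dependent;
  reproducing another implementation's exact map sizes is out of reach and
  not attempted.
* The repositioning confidence counts unclassified drugs in the
  denominator but no numerator; whether the original corpus tables did
  the same cannot be verified from printed cluster compositions, so this
  is flagged as an assumption in the documentation.
* Multi-class drugs support every class they carry when tallying cluster
  majorities; alternative conventions (fractional support, resolved
  single labels) would shift confidences for multi-class-heavy clusters.
* Weighted (non-equal) view averaging is accepted by `average_ddr()`
  callers composing their own matrices, but the validated method uses
  equal weights only.
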