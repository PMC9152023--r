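---
title: "Methods: c-fos functional connectivity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: c-fos functional connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosnet)
```

# The problem

Counts of c-fos⁺ nuclei proxy recent neuronal activity. Quantified across
many brain regions in each animal of a small cohort, they support two
complementary analyses: a *regional screen* for group differences in
activation, and a *functional connectivity* analysis in which the
across-animal covariation of counts between two regions is read as evidence
that the regions were co-active. `fosnet` implements both for a 2 × 2
between-subjects design (sex × training status), together with the
graph-theoretic machinery used to characterize the resulting networks and
identify hub regions.

This vignette records the model, the conventions adopted where the
procedure is genuinely underdetermined, and what the synthetic validation
does and does not establish.

# Ingest and matched representation

Raw data are per-section bilateral counts. Aggregation is a two-stage mean:
hemispheres within a section (using the available side when one is
missing — discarding a usable hemisphere would waste scarce animals), then
sections within a region. Aggregated values are real numbers, not integers.

Sectioning damage and imaging failures leave missing animal × region cells,
and the correlation stage requires every retained animal to have every
retained region ("matched representation"). No standard algorithm exists
for choosing the subset to keep; the package uses a deterministic greedy
rule: while missing cells remain, drop the most-missing *region* if it is
absent from more than `max_region_missing_frac` (default 0.5) of the
remaining animals, otherwise drop the most-missing *animal*, breaking ties
toward the first in table order. Animals are deliberately cheaper to drop
than regions only when a region is broadly absent, because region count is
the analysis currency. The exclusion report lists everything dropped, with
reasons. This policy is a declared convention, not a reconstruction of any
particular lab's adjudication.

# Regional screen

Per region, a two-way between-subjects ANOVA on the (untransformed) counts
with factors sex and training. Group sizes of 3–5 are typically unbalanced,
so main effects and interaction are tested with Type III sums of squares
under sum-to-zero coding (`car::Anova` on a `contr.sum` fit); on balanced
fixtures Type II and III agree, which the tests assert. The error degrees
of freedom are N − 4. Regions with zero error variance are flagged
degenerate rather than raising an error, so one pathological region cannot
abort a 112-region screen.

Planned pairwise comparisons use Fisher's LSD: the pooled error mean square
and its degrees of freedom from the same region's ANOVA,
t = (m̄ₐ − m̄ᵦ)/√(MSE(1/nₐ + 1/nᵦ)), two-tailed. By default the
trained-male vs trained-female contrast is computed only in regions whose
interaction is significant at α (the usual motivation for running it); a
flag tests it everywhere instead. Screening is region-wise at α = 0.05 with
no multiplicity adjustment by default — matching how such screens are
reported — with optional Benjamini–Hochberg columns for users who want
them.

# Correlation matrices and edge thresholds

Within each of the four groups, Pearson's r is computed for all region
pairs across animals, with two-tailed p-values from
t = r√((n−2)/(1−r²)) on n − 2 df. Groups need n ≥ 3; regions with zero
within-group variance yield flagged-undefined entries that can never become
edges. Two-tailed p-values are used because the edge thresholds they imply
at small n (r\* = t\*/√(t\*² + n − 2): 0.95 at n = 4, 0.997 at n = 3,
α = 0.05) are the values conventionally quoted for this design; positivity
is enforced at edge selection rather than through a one-tailed test. No
multiplicity correction is applied across the ~6 000 pairs — at these
sample sizes any correction would empty the network, which is why the
downstream null-model validation exists.

An edge joins two regions iff r > 0 and p is *strictly* below the
threshold.

# Graph measures

All measures are computed on the binary undirected graph; a region is
*active* if it has at least one edge, and isolated regions are excluded
from centrality normalization and from null-model matching.

- **Degree**; **betweenness** normalized by (N−1)(N−2)/2 over active nodes,
  so it reads as the fraction of shortest paths through the node. Hub
  identification is rank-based, so the normalization constant is
  immaterial there.
- **Transitivity** (global clustering): 3 × triangles / connected triples;
  undefined without triples.
- **Assortativity**: Pearson correlation of endpoint degrees over both
  edge orientations; undefined (flagged) on degree-regular graphs.
- **Characteristic path length**: mean shortest path over *reachable*
  pairs of active nodes. These networks are routinely disconnected;
  treating unreachable pairs as infinite would poison the mean, so they
  are excluded, and the value is undefined only when no pair is reachable.
- **Small-worldness**: S = (T/⟨T_ER⟩)/(L/⟨L_ER⟩), both normalized against
  100 Erdős–Rényi graphs matched on active-node and edge counts. G(n, m)
  with the exact edge count is used rather than G(n, p) because the
  matching is tighter at small m. Ensemble means skip replicates where a
  measure is undefined.

## Markov clustering

MCL runs on the adjacency with unit self-loops: column-normalize, then
iterate expansion (matrix square) and inflation (elementwise power,
renormalize), pruning entries below 1e−10, until the maximum elementwise
change falls below 1e−8 (hard cap 200 iterations — exceeding it is an
error, not a silent result). Clusters are read from attractor rows;
attractors containing each other's attractor node merge into one system,
and a node supported by several systems goes to the largest cluster (ties
to the lowest index), making the partition deterministic and invariant to
region order.

The inflation hyperparameter is chosen per network by maximizing
Newman–Girvan modularity Q = Σ_c (e_cc − a_c²) over a grid (default
1.1–3.0 by 0.1, ties to the smallest inflation). Q is the declared
modularity variant; nothing in the procedure depends on its specific
normalization beyond ordering the candidate partitions.

# Null models

Randomized controls are built by double-edge swaps — pick two edges (a,b),
(c,d), replace with (a,d), (c,b) unless a self-loop or duplicate would
result — which preserve every node's degree exactly, hence also the
active-node set, edge count, and degree distribution. Ten attempted swaps
per edge (the common Maslov–Sneppen convention) separate replicates;
graphs with no valid swap (a triangle) legitimately return unchanged.
Connectedness is *not* enforced: the data networks are themselves
disconnected. The ensemble records each measure per replicate and the data
value's empirical quantile with the midpoint convention
(#less + ½·#equal)/n.

The threshold sweep rebuilds the network at 20 thresholds (p < 0.005 to
p < 0.1 in steps of 0.005), comparing data to a fresh null ensemble at
each; thresholds that empty the network are reported as undefined rows
rather than dropped.

# Hubs and robustness

A hub ranks in the top 20 % of active nodes for *both* degree and
betweenness. The cutoff index is ceiling(0.2 · N_active); ties with the
value at the cutoff are included, so the result cannot depend on node
order — and a qualifying value must be positive. The positivity clause
resolves a degeneracy of the pure ties-inclusive rule: in a star graph
every leaf ties at betweenness 0 with the cutoff value, and a rule without
the clause would crown every leaf a hub; a node lying on no shortest path
is not a meaningful "top-betweenness" node. On a fully tied cycle, by
contrast, every node genuinely shares the top value and all are hubs.
Whether the original procedure used ceiling or floor and how it broke ties
is not documented anywhere we know of; these are declared conventions.

Hub robustness builds the base network (p < 0.05) plus nine pruned ones
(p < 0.005 … 0.045) and counts, per region, how many of the ten keep it as
a hub. Ties share a rank, and the "most robust hub" is reported as a
possibly-plural set.

# The synthetic cohort generator

`generate_cohort()` draws lognormal counts:
count = exp(μ_r + β_r·trained + s_r·female + γ_r·female·trained +
Σ_k L_rk f_ka + ε_ar), ε ~ N(0, σ²). The lognormal form keeps counts
positive with mild right skew and makes effects multiplicative, both
realistic for c-fos.

Defaults mirror a brain-wide threat-conditioning study design: groups of
n = 4 (naive) and n = 3 (trained) per sex; 112 regions; a twofold training
effect in 93 regions; a sex effect in 5 and a sex × training interaction
in 8 regions; baseline means spanning ~20–200 counts; σ = 0.1 with block
loadings 0.3, giving within-block correlations of 0.9 ("integrated
clusters" of co-active regions) and a marginal CV of ~0.3, in the range
reported for regional c-fos counts. Keeping the marginal dispersion modest
matters beyond realism: Pearson correlation on heavily dispersed lognormal
counts is dominated by a handful of high-count animals, and early versions
of the generator with CV ≈ 1.4 produced raw-scale correlation matrices
whose structure was mostly leverage artifact.

Two deliberate design choices deserve emphasis:

- **Empirical factor covariance.** For groups with more animals than
  factors, latent factor scores are drawn with
  `MASS::mvrnorm(empirical = TRUE)`, so the *sample* covariance of the
  factors is exactly the identity. With iid draws, chance between-factor
  correlations (sd ≈ 0.14 at n = 50) pass the loose edge threshold
  coherently across whole block pairs and masquerade as planted structure;
  recovery tests should probe what was planted, not what sampling noise
  invented. Tiny (paper-sized) groups fall back to iid draws, where the
  near-unity critical r filters chance covariance anyway.
- **Hub geometry.** Each planted hub loads on its home block's factor
  (0.4) and on a bridge factor (0.35) shared with 7 of the 12 regions of a
  dedicated satellite block. This gives the hub top degree and top
  betweenness — its cross-cluster edges survive even the strictest pruning
  threshold — while leaving the satellite a distinct community. The
  obvious simpler geometry (a hub loading symmetrically on two large
  blocks) fails structurally: once its edges to both blocks survive a
  threshold, the hub forms a complete star over both, and under MCL a node
  adjacent to *all* members of two dense blocks merges them at every
  inflation (we verified this against an independent implementation). A
  hub that borders only part of a neighboring community is also the more
  faithful picture of hubs sitting between clusters.

`planted_truth()` exposes the implied cluster labels (argmax |loading|),
hub set, and effect flags for recovery tests.

## What the synthetic validation shows — and does not

Passing recovery tests establishes that the pipeline detects planted
block-correlation structure, selects sensible MCL inflations, and ranks
planted bridging regions as top robust hubs at n = 50 per group. It does
not establish that real c-fos networks satisfy the generator's
assumptions: real counts have region-dependent overdispersion, detection
artifacts correlated across neighboring sections, and covariance that is
not low-rank block structure; and real cohorts of n = 3–4 sit in a regime
where hub identities are intrinsically noisy (the tests show exactly that).
Conclusions about specific hub regions in real data should rest on the
robustness ranking and null-model comparisons, not on a single network.

# Numerical conventions and problem sizes

Degenerate inputs are flagged, not fatal: zero-variance regions
(correlation undefined), degree-regular graphs (assortativity), triple-free
graphs (transitivity), unreachable node sets (path length). Thresholds use
strict inequality. All stochastic steps (generation, rewiring, ER
ensembles, the pipeline) are seeded; reruns are bit-identical, which the
manifest's file hashes make checkable.

The shipped test suite sizes simulations for depth per unit time: oracle
equivalence sweeps 200 random graphs of ≤ 9 nodes against exhaustive-path
oracles; the null-model contract uses 1000 rewirings of a 50-region
network and 100 replicates per threshold across the 20-point sweep;
recovery uses 20 seeded cohorts at n = 50 per group; calibration uses
500-region null cohorts. The full-scale analysis (1000 replicates per
threshold) is the pipeline default.

# Known limitations

- Pearson correlation on raw counts is leverage-sensitive at these sample
  sizes; rank or log-scale correlation are principled alternatives the
  package does not currently expose.
- MCL resolution interacts with modularity selection: communities far
  below the modularity resolution limit (≈ √(2m)/2 internal edges) can be
  absorbed by their neighbors regardless of inflation.
- The matched-representation filter is greedy, not optimal; pathological
  missingness patterns exist where a different deletion order keeps more
  data.
- Partial correlations, weighted networks, and alternative community
  methods are out of scope.
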