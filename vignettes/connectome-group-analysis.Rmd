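---
title: "Group analysis of structural connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group analysis of structural connectomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msconn)
library(dplyr)
```

`msconn` implements a group-level graph-theoretical analysis of structural
brain networks reconstructed from diffusion-MRI tractography, specialised
to a three-group design over the motor–sensory system: patients who
developed intraoperative stimulation-related epilepsy (`Ep`), patients who
did not (`nEp`), and healthy controls (`con`). This vignette documents the
statistical methods, the synthetic cohort model, and the numerical choices.

## 1. Networks and atlas

Each subject contributes four symmetric, non-negative adjacency matrices
over the same node set, one per edge weighting:

- **binary** — 1 if any streamline connects two parcels;
- **FA** — mean fractional anisotropy along the connection, in [0, 1];
- **FN** — streamline (fiber) count, ≥ 0;
- **FL** — mean tract length in millimetres.

The packaged atlas contains 28 motor–sensory subregions (14 bilateral
pairs spanning precentral, paracentral, postcentral and superior-frontal
parcels). Tumor-infiltrated parcels cannot be segmented reliably, so a
per-study exclusion list removes them for *all* subjects; the default
exclusion removes 6 left-hemisphere parcels, retaining 22 nodes. All
matrices are validated on construction: square and symmetric to tolerance,
zero diagonal, weighting-specific ranges, node set matching the atlas.

## 2. Consistency backbone

Tractography produces spurious low-consistency edges. We retain an edge if
it is present (FN > 0) in strictly more than a threshold fraction of
subjects — 75% by default — pooled over all groups, and apply the
resulting group-level mask to every subject before computing metrics. A
pooled (rather than per-group) mask keeps the edge universe identical
across groups so group comparisons are not confounded by differing
supports; `scope = "per-group"` (intersection of per-group masks) is
available.

## 3. Graph metrics

Weighted analyses convert weights to lengths by the reciprocal convention
`len = 1/w` (stronger connections are shorter), then compute shortest
paths with Dijkstra's algorithm (via igraph). For a distance matrix `d`
over `N` nodes:

- **Global efficiency** `E_glob = mean(1/d_ij)` over all ordered pairs,
  with unreachable pairs contributing 0 — this makes `E_glob` well defined
  on disconnected graphs.
- **Characteristic path length** `L_p` is the mean of `d_ij` over
  *reachable* pairs (default), with the companion `unreachable_fraction`
  reported so disconnection is never silent; a harmonic-mean variant is
  available.
- **Nodal efficiency** `E_nodal(i) = mean(1/d_ij, j ≠ i)`.
- **Degree centrality**: binary degree on binary matrices, strength (sum
  of weights) otherwise.
- **Betweenness centrality**: fraction of all-pairs shortest paths through
  a node, normalised by `(N−1)(N−2)/2`.
- **Clustering coefficient**: binary triangle density per node, or the
  Onnela weighted form — the diagonal of `(W/max(W))^(1/3)` cubed,
  divided by `k(k−1)`.
- **Local efficiency**: global efficiency of each node's neighbour
  subgraph.

### Small-world indices

`gamma = C_p/C_rand`, `lambda = L_p/L_rand`, `sigma = gamma/lambda`,
where `C_rand`/`L_rand` are means over an ensemble (default 100) of
degree-preserving Maslov–Sneppen rewirings of the observed network
(10 accepted double-edge swaps per edge). Rewiring preserves each node's
degree exactly and permutes the weight multiset over the rewired edges.
Every null network has its own derived seed, so results are reproducible
and individual nulls are recomputable in isolation.

## 4. Network-based statistic (NBS)

Edge-wise mass-univariate testing over ~100 backbone edges has no power
after family-wise correction; the NBS controls the family-wise error at
the level of *connected components* instead:

1. One-way ANOVA F per edge across the three groups (vectorised over
   edges).
2. Primary threshold: the `1 − alpha` quantile of `F(k−1, n−k)`
   (default `alpha = 0.01`); suprathreshold edges form components.
3. Permutation null: group labels are randomly reassigned (preserving
   group sizes) 5000 times; each permutation records its maximum
   component statistic.
4. `p_fwe = (1 + #{null ≥ observed}) / (n_perm + 1)` per observed
   component (add-one estimator, so p-values are never zero).

The component statistic defaults to **intensity** (the sum of `F −
threshold` over the component's edges) rather than extent (edge count).
Rationale: the planted effects of interest are strong but confined to one
or two edges; under the extent statistic a single-edge effect can never
beat a null distribution whose maxima are themselves ≥ 1 whenever any
noise edge crosses the threshold, whereas intensity accumulates the
strength of the effect. Extent remains available
(`component_stat = "extent"`) and favours spatially broad, weak effects.

Edges with zero total variance get F = 0; perfect group separation
(zero within-group variance with real between-group spread) is capped at
a sentinel F = 1e12 and flagged, keeping permutation maxima finite.

## 5. Group statistics

Per (scope, metric, node, weighting) cell, the per-subject values are
z-transformed against the pooled mean and SD — topological properties
live on incommensurate scales across weightings, and z-scoring puts the
ANOVAs on a common footing (the F statistic itself is affine-invariant).
One-way ANOVA p-values are then adjusted by Benjamini–Hochberg within
FDR families chosen to match how results are tabulated: nodal properties
across the 22 nodes within one metric × weighting; global properties
across metrics within one weighting. Cells passing `q < 0.05` receive
uncorrected pairwise post-hoc tests (Welch by default — robust to the
unequal variances of small patient groups; Tukey HSD optional).

Two helpers reproduce demographics-table statistics: an unpaired t-test
reconstructed from printed `mean ± SE` summaries
(`t = (m_a − m_b)/sqrt(se_a² + se_b²)`, `df = n_a + n_b − 2`) and
Fisher's exact test on 2×2 / 2×3 count tables.

## 6. Synthetic cohort model

No patient data ship with the package; the generator produces cohorts
with the statistical structure the downstream stages must detect, so the
entire pipeline is testable offline.

**Template.** One binary support shared by all four weightings
(deterministic tractography derives every weight from a single streamline
set): non-hub pairs connect with probability 0.35, hub pairs (bilateral
medial area 6, A6m_L/A6m_R) with probability 0.9 and at least 80% hub
coverage enforced, homotopic left/right pairs always connect, and the
support is redrawn until connected. Template weights: FN lognormal
(meanlog 4, sdlog 0.8; hub edges ×3), FA truncated normal (0.5 ± 0.1 on
(0.2, 0.8) — the lower bound reflecting the usual FA tracking floor of
0.2), FL truncated normal (60 ± 15 mm on (10, 150); hub edges ×1.6).

**Subjects.** Each subject multiplies every template weight by i.i.d.
lognormal noise (sdlog 0.05, mean-corrected), then three group-level
mechanisms apply:

1. **Planted edge effects** (multiplicative reductions, default 0.6):
   FA at A6m_L–A6m_R in `Ep` only; FN at the two trunk/limb connections
   (A123tru_L–A4ul_L, A123tru_R–A4t_R) in both patient groups.
   Multiplicative effects keep FA in range and encode the "patients
   show lower FA/FN" directionality without inventing units. A
   multiplier `m` shifts the affected group's edge mean by exactly `m`
   in expectation — a tested invariant.
2. **Edge dropout**: each subject loses each non-hub, non-homotopic
   template edge with a per-group probability (Ep 0.15, nEp 0.08,
   con 0.02; zeroed across all weightings so the subject keeps one
   shared support). Purely multiplicative effects cannot move binary or
   FL-weighted metrics; dropout produces the global efficiency deficits
   in those weightings.
3. **Hub attenuation**: all hub-incident weighted edges are multiplied
   by 0.9 in the `Ep` group. This encodes the hub degradation at the
   bilateral medial area 6 — a marked drop of A6m degree centrality and
   nodal efficiency — which a single-edge effect diluted over ~21 hub
   connections cannot produce. The value 0.9 comes from an a-priori
   power argument: a 10% strength shift against a hub-strength SD of
   roughly 5%/sqrt(21) is decisive at n = 10 per group.

`null_cohort()` strips all three mechanisms (effects removed, dropout
equalised to the group mean, attenuation off), leaving groups
exchangeable — the type-I-error harness for the NBS and FDR machinery.

**Limitations.** Noise is i.i.d. per edge with no spatial
autocorrelation; dropout is independent across edges; there is no tumor
mass-effect deformation. The generator targets the *statistical*
signature of the findings, not diffusion biophysics.

## 7. Reproducibility and problem sizes

Every stochastic stage takes an explicit integer seed; the pipeline
derives per-stage seeds from one master seed (`master + 1000·stage +
offset`), so each stage is independently reproducible and all derived
seeds stay far below 2^31. Default problem sizes — 3 × 10 subjects,
22 nodes, ~100 backbone edges, 5000 permutations, 100 small-world nulls —
run end-to-end in well under two minutes on one CPU. The test suite
validates correctness against independent oracles (Floyd–Warshall
distances, exhaustive-path betweenness, lm-based ANOVA, hand-rolled
step-up FDR, full-enumeration Fisher) and operating characteristics by
simulation (NBS and FDR type-I error ≤ 0.07 on null cohorts; planted
effects recovered in ≥ 80–90% of seeds).

```{r example, eval = FALSE}
cohort <- generate_cohort(sim_config(n_per_group = 10, seed = 42))
mask <- consistency_mask(cohort, threshold = 0.75)
nbs <- nbs_test(cohort, "FA", mask, nbs_config(n_perm = 5000, seed = 43))
glance(nbs)
metrics <- compute_metrics(cohort, mask)
stats <- compare_groups(metrics)
```
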