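---
title: "Methods: building and comparing structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and comparing structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectoscope)
```

This vignette documents the models, conventions and numerical choices
behind the package, in the order the pipeline applies them.

## The data model

A study is a cohort of subjects, each contributing a symmetric,
non-negative integer matrix of streamline counts between all pairs of
regions of a fixed whole-brain atlas (the packaged default has 116
macrolabel regions: 45 bilateral cortical/subcortical pairs, 9 bilateral
cerebellar pairs, 8 vermis segments). Region masks are registered once per
study, so per-region voxel counts are atlas-level, not subject-level,
quantities. The voxel counts shipped with the packaged atlas are
synthetic (log-normal around 500 voxels, frozen once); real studies
should substitute their own mask sizes.

## Network construction

**Voxel normalization.** Streamline counts are confounded by regional
volume: larger target masks catch more streamlines. Each count is
divided by the voxel count of the target mask. For a symmetric count
matrix this ratio is direction-dependent, so the two directed ratios are
averaged: `w_ij = (c_ij/v_i + c_ij/v_j)/2`. This keeps the weight matrix
symmetric while honoring the per-target normalization; with uniform
voxel counts it reduces to a plain rescale.

**Proportional thresholding** (default target density 0.5). All weights
are first divided by the single maximum edge weight pooled over the whole
cohort, so stored weights are expressed relative to a cohort-wide
reference. Edge *selection* is unaffected by that choice — per-network
removal by weight rank is scale-invariant — but it makes stored weights
comparable across subjects, which matters for strength-based measures.
Then, per network, the weakest nonzero edges are removed until the
density is at most the target; a network already below target keeps all
its edges. We deliberately threshold per network rather than applying one
pooled cut, because group densities are meaningful summaries only if
every subject is held to the same budget.

**Pruning** (default fraction 0.10). `floor(0.10 × E)` of the weakest
nonzero edges are removed per network to suppress residual spurious
connections. In both threshold stages, ties are broken deterministically
by lexicographic node-label pair, so identical inputs always produce
identical networks.

**Degenerate inputs.** An all-zero cohort cannot be thresholded (error);
a zero voxel count is rejected at atlas construction.

## Graph measures

Shortest paths are computed on the connection-length matrix
`len = 1/w`: strong connections are short. This convention is applied
uniformly to characteristic path length, global efficiency and
betweenness centrality.

**Total-weight normalization.** Raw path-based measures scale with the
weights (multiplying all weights by `c` multiplies efficiency by `c` and
divides path length by `c`), which makes them incomparable across
subjects whose overall streamline mass differs. The package therefore
divides all weights by the network's total weight sum before computing
the integration and segregation measures (mode `"total"`, the default;
`"none"` is available and is used by the brute-force oracle tests). The
normalization mode is recorded in every output table. The exact algebraic
form of a "total weights" normalization is a convention, not a theorem;
dividing by the weight sum is the choice here because it makes all three
global measures exactly invariant to global rescaling — the property the
normalization exists to provide.

**Disconnected pairs** are excluded from the characteristic-path-length
mean and their count is reported alongside (attribute
`disconnected_pairs`); efficiency handles them natively as zero inverse
distance. At ~30% density the thresholded networks are connected in
practice, but the policy must be defined for edge cases.

**Clustering** uses the Onnela geometric-mean-of-triangle-weights
formulation with weights rescaled by their maximum — the default in the
standard brain-connectivity toolboxes. The max-rescale makes it
scale-invariant regardless of normalization mode.

**Betweenness** divides raw pair dependencies (unordered pairs,
equal-length multiplicity shared fractionally) by `(n−1)(n−2)`, giving
values in [0, 1].

## Communities and hubs

**Consensus Louvain.** Louvain is greedy and order-dependent, so a single
run is an unreliable partition. The package runs it `n_iterations = 100`
times, each on an independently permuted node order with its own RNG
substream, then forms the standard consensus: node-pair agreement matrix
over iterations, thresholded at 0.5, re-clustered with Louvain until all
iterations agree (capped at 20 rounds with a warning; in practice planted
networks converge in 1–2 rounds). Module ids are assigned by descending
module size. The reported Q is always recomputed from the consensus
assignment with the package's own weighted Newman–Girvan implementation,
and the best single-run partition is retained for comparison. Q in
0–0.3 is interpreted as random-like; the resolution parameter is fixed
at 1.

**Hubs.** A node is a hub if its degree or strength is at least one
sample SD (n−1 denominator over the nodal values) above the network mean
on the *group-averaged* network; the two bases are evaluated
independently, and a node may be a hub on both. When the SD is zero
(all nodal values equal) the rule would make every node a hub, so the
degenerate case is defined as "no hubs".

**Participation coefficient** uses binary edge counts per module by
default (`PI_i = 1 − Σ_m (κ_im/k_i)²`), matching degree-based hub
tables; a strength-weighted variant is available via `weighted = TRUE`.
Hub classes: provincial `PI ≤ 0.3`, connector `0.3 < PI ≤ 0.75`,
unclassified above — the literature convention for
participation-coefficient hub taxonomy. Because published sources
occasionally state the two bands the other way around, an
`convention = "inverted"` flag exposes the swapped reading.

**Module matching and migration.** Group-level partitions are matched by
maximizing total node overlap on the contingency table (exhaustive over
pairings up to 8 modules — optimal by construction; greedy descent
beyond that). Migration is reported per matched module as the signed
percent size change `(size_B − size_A)/size_A × 100` and per node as
(node, from, to).

## Group inference

**Global metrics** are compared by split-plot ANOVA: group is the
between-subject factor, graph measure the within-subject factor. Only
this design reproduces the correct denominator degrees of freedom for a
three-group, three-measure study (e.g. 16/17/15 subjects: group df
(2, 45), interaction df (4, 90)). Post hoc univariate per-metric F-tests
run only when the group effect or the interaction is significant at .05.

**Nodal metrics** are compared by label-permutation tests. The statistic
is the difference of group means — reported as the standard difference
score (SDS) — with a two-sided p from the add-one estimator
`p = (1 + #{|null| ≥ |obs|})/(n_perm + 1)`, which cannot reach zero and
is valid under exchangeability. Exhaustive enumeration replaces sampling
on request for small groups. The default `alpha = 0.016` is 0.05
Bonferroni-corrected over the three nodal metrics; node-level
multiplicity is not additionally corrected, which mirrors common practice
in nodal connectome comparisons. One set of permutations is shared
across nodes within a metric (standard for nodewise network inference);
ties with the observed statistic count as exceedances.

**Clinical correlations** are Spearman rank correlations (midrank ties,
two-sided p, `exact = FALSE`); zero-variance input is flagged as
undefined rather than propagated. **Demographics** use pooled-variance
two-sample t tests (Welch by flag) for continuous variables — including
a summary-statistic mode working from published (mean, SD, n) triples —
and Fisher's exact test for categorical ones.

## The synthetic cohort generator

The generator emulates the *structure* of a tractography study, not the
physics of diffusion imaging: its unit of output is the streamline-count
matrix that tractography would emit.

- **Communities**: regions are split into `n_modules = 5` contiguous
  near-equal blocks in atlas order.
- **Anatomical backbone**: a single Bernoulli edge mask is drawn per
  cohort and shared by all subjects (white-matter anatomy is common
  across individuals after registration), with edge probability 0.75
  within modules and 0.22 between. This puts raw individual densities
  near 32% and — because edge *locations* are consistent across subjects
  — keeps group-averaged densities near 30%, the canonical mammalian
  connectome density. Without a shared backbone, averaging 16 independent
  sparse networks would drive the group network toward full density.
- **Counts**: negative-binomial per edge (size 2, overdispersed as
  empirical streamline counts are), with mean proportional to
  `within_weight_scale` (30) or `between_weight_scale` (10) times the
  product of endpoint voxel counts — so voxel normalization downstream is
  non-trivial — times the hub multipliers.
- **Hubs**: nine subcortical/parietal regions (bilateral putamen,
  thalamus, hippocampus, precuneus, right caudate) get multiplier 1.8 on
  expected counts *and* `sqrt` of the multiplier product on backbone
  probability (capped at 1): real hubs are both more strongly and more
  widely connected, and both bases of the hub criterion must be able to
  find them.
- **Group effects**: multiplicative (or additive) changes to one
  region's row/column in one group's matrices, rounded back to integers
  with symmetry preserved — the ground truth for permutation tests. The
  defaults plant a motor-area increase in one patient group and
  insula/cingulate decreases in the other.
- **Clinical covariates**: drawn from zero-truncated normal marginals
  patterned on a typical focal-dystonia cohort (onset ~37 ± 12 y,
  duration ~16–19 ± 10 y, movement/disability severity scores); patient
  age is onset + duration. Requested rank correlations with a region's
  nodal strength are enforced by a Gaussian copula: the target Spearman
  `rho_s` is mapped to the normal-copula correlation `2 sin(π rho_s/6)`
  and marginals applied by quantile transform, so ranks are controlled
  directly and targets ±1 are achieved exactly.
- **Determinism**: one seed governs mask, counts, effects and clinical
  draws; identical configs are byte-identical on disk.

What passing tests on these cohorts do **not** show: robustness to
registration error, atlas misparcellation, tractography false positives
with distance bias, subject-specific anatomy, or non-stationary
module sizes — none of which the generator emulates. Recovery results on
synthetic cohorts are a correctness floor, not an empirical validation.

## Problem sizes and tolerances

The test suite verifies path length, efficiency, betweenness and
participation against a brute-force exhaustive path enumeration on 200
random connected graphs of up to 7 nodes at tolerance 1e−9; permutation
type-I error on 2,000 null datasets at 500 permutations; planted-effect
power on 50 cohorts of 16 + 16 subjects; community and hub recovery on
16–20 cohort seeds with 50–100 Louvain iterations. These sizes were
chosen so the full suite runs in a few minutes on one CPU while keeping
every statistical check at its intended resolution; the underlying
functions default to study-scale settings (100 iterations, 10,000
permutations).

## Known limitations

- Proportional thresholding and 10% pruning are the only schemes offered;
  consistency- or absolute-thresholding are out of scope.
- The consensus procedure can fail to stabilize on structureless (random)
  networks; it then returns the current majority partition with a
  warning, which is the honest answer for a network with no communities.
- Hub detection operates on group-averaged networks only; per-subject hub
  statistics are not implemented.
- No network-based statistic (NBS), FDR across nodes, or
  covariate-adjusted group comparisons.
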