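---
title: "An expanded UniFrac toolbox: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An expanded UniFrac toolbox: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what each dissimilarity measures, what the rarefaction-stability diagnostic
quantifies, which knobs matter, and what the synthetic data generators do
and do not emulate.

## The branch-mass model

Every metric here is computed from one object: the **branch mass table**.
For a rooted tree with branch lengths `b_i` and a sample with proportional
OTU abundances `p`, the mass of branch `i` is the sum of `p` over the
leaves of its subtree (`branch_mass()`). The root carries no branch, so all
sums run over non-root edges. Masses are additive (a parent branch's mass
is the sum of its children's plus any directly subtended leaf), and for any
non-empty sample the root's child branches jointly carry mass 1.

On top of this table the four UniFrac weightings are branch-length-weighted
L1 distances between per-branch transformed masses:

| metric | transform of mass `m` | normalizer | range |
|---|---|---|---|
| unweighted | `1{m > 0}` | covered (union) branch length | [0, 1] |
| weighted | `m` | total branch length | [0, 1] |
| information | `-m log2(m)` (0 at m = 0) | total branch length | ≥ 0 |
| ratio | `m / gm(collapsed composition)` | total branch length | ≥ 0 |

The weighted/information/ratio normalizer is the sum of **all** branch
lengths of the tree, exactly as the defining formulas are written — not the
abundance-weighted normalization used by the 2007 weighted UniFrac. OTUs
present in the tree but absent from the table contribute zero mass while
their branch lengths still widen that normalizer; this is a deliberate
contract (`distance_matrix(..., intersect_taxa = TRUE)` reconciles the two
leaf sets up front when you want the table's tree instead).

For the information weighting, `I(p) = -p log2(p)` is measured in bits with
the entropy convention `0 log 0 = 0`; it vanishes at both abundance
extremes and peaks at `p = 1/e`. Below a proportion of about 0.2 the curve
lies above the identity and rises much faster from zero, which is what
gives the metric its sensitivity to small abundance changes in rare taxa —
note that the *pointwise slope* drops below 1 already at
`p = 2^-(1 + 1/ln 2) ≈ 0.18`, so the honest statement is about the curve
and its chord from zero, not about every difference quotient.

For the ratio weighting, the collapsed composition at branch `i` is the
subtree's combined proportion together with the individual proportions of
every leaf outside the subtree; its geometric mean is computed as the mean
of logs for numerical stability (the contract is value equality, not
evaluation order). Because a geometric mean is undefined at zero, ratio
UniFrac demands strictly positive proportions and the pipeline runs
`replace_zeros()` first.

## Zero replacement

`replace_zeros()` implements a Bayesian-multiplicative treatment: each zero
cell receives a prior pseudocount of 0.5 on the count scale, positives are
adjusted multiplicatively and the sample is re-closed to 1. Concretely,
with sample total `N` and `z` zeros, a zero becomes `0.5 / (N + 0.5 z)` and
a positive count `x` becomes `x / (N + 0.5 z)`. This preserves all ratios
among observed counts, keeps every replaced value strictly below the
smallest observed proportion, and never produces a negative or zero entry
regardless of sparsity. It is *not* a numerical reimplementation of any
particular published zero-replacement routine; the contract is "strictly
positive, multiplicative, closure-preserving", which is what the ratio
weighting needs.

## Rarefaction and its defaults

`rarefy()` draws each sample down to a common depth without replacement
(one multivariate hypergeometric draw per sample), processing samples in
label-sorted order from a single seeded stream so that the same seed gives
the same table on any platform and input row order. The default depth is
the minimum sample total. `distance_matrix()` rarefies **only for
unweighted UniFrac** by default — the binary weighting is the one that
assumes a common depth — while weighted, information, ratio and Bray-Curtis
run on the full counts; `rarefy_first` overrides this in either direction
(the stability experiment forces rarefaction for every metric, because its
whole point is to compare the metrics on identical rarefied inputs).

A seed is required wherever rarefaction happens: a rarefied table is a
random point estimate and is not reproducible without one.

## Tree handling

Trees are parsed and written through `ape` (`parse_newick()` validates
balance, label uniqueness and non-negative lengths; edges without lengths
parse as 0 with a warning, internal node labels are ignored). Midpoint
rooting — the standard UniFrac rooting when no outgroup exists — is
delegated to `phangorn::midpoint()`; it conserves total branch length, and
ties between equal-diameter paths resolve by that routine's own
deterministic rule. Zero-length branches are retained: they contribute
nothing to any UniFrac sum, so contracting them is cosmetic.

Per-pair tree **pruning** (restricting the tree to the OTUs present in each
pair of samples, as some UniFrac implementations do) is available via
`distance_matrix(..., prune = TRUE)` but off by default. Pruning changes
the normalizer per pair and demonstrably breaks the triangle inequality for
weighted UniFrac — the test suite constructs a three-sample instance where
`d(A,C) > d(A,B) + d(B,C)` — so pruned results are flagged
`is_metric = FALSE`, as are ratio UniFrac and Bray-Curtis in general.

## Ordination and the stability diagnostic

`pcoa()` is classical metric scaling: double-centering of `-D²/2`,
eigendecomposition, coordinates scaled by the square root of the positive
eigenvalues. Axes with non-positive eigenvalues are dropped but counted —
a negative eigenvalue is the fingerprint of a non-Euclidean input (e.g. a
pruned-tree dissimilarity). Variance explained uses positive eigenvalues
only, with no Lingoes/Cailliez correction, so percentages match what plain
PCoA plots report. Each axis is oriented so its largest-magnitude
coordinate is positive, making ordinations deterministic.

`procrustes_align()` overlays one configuration onto a reference by
translation, orthogonal rotation (reflections allowed) and, by default,
isotropic scaling, solved via `vegan::procrustes()`; the no-scaling case is
exposed with `scale = FALSE` since either convention is defensible for
overlaying ordinations. Disparity is the residual sum of squares over the
centred reference's sum of squares.

`rarefaction_stability()` chains the pieces: `n` rarefactions (instance `i`
uses `seed + i`, for auditability), one distance matrix and PCoA per
instance and metric, Procrustes overlay of each ordination onto instance 1
using the first two axes (the plotted plane; configurable via `n_axes`),
and the per-sample relative PC1 deviation

```
V_res = |V1 - Vi| / range(V1, Vi)
```

where the range is max minus min of the **pooled** values of both PC1
vectors — one scalar per instance pair. A per-sample range of two numbers
would make every deviation equal to 1 whenever the coordinates differ at
all, which carries no information; the pooled range measures displacement
against the spread of the configuration, and makes `V_res` invariant to
rescaling both ordinations together. Each instance is summarized by its
maximum and median `V_res`; samples whose aligned PC1 changes sign between
instances 1 and 2 are reported as *migrations* — the samples that would
have switched apparent clusters had the experiment been run once.
`summarize_ellipse()` fits the usual bivariate-normal confidence ellipse
(mean, covariance, chi-square radius) to the max-vs-median cloud.

## What the generators emulate

All experiments run on synthetic data; each generator is
seed-deterministic.

- `simulate_uniform_dataset()` is the null dataset for the stability
  comparison: 60 samples drawn from **one** common sparse, long-tailed
  composition (log-normal, sd 2 on the log scale, 554 OTUs) with read
  depths log-uniform between 659 and 17176 — the depth spread of a typical
  single-body-site survey. Any structure found in it is a sampling
  artifact. The tree is a random coalescent topology with exponential
  branch lengths (mean 0.1); 25 pendant branches are stretched tenfold, and
  those long branches are placed on OTUs in a rare-but-retained band of
  total counts (120–1200 by default). That placement is deliberate: a long
  *isolated* branch is a divergent taxon without close relatives, and in
  amplicon surveys such taxa are rare ones near the detection limit —
  stretching branches of abundant taxa, whose presence never flips under
  rarefaction, would not produce the tree shape this diagnostic is about.
- `simulate_two_group_dataset()` mixes a shared baseline with
  group-specific profiles concentrated on the two clades flanking the root;
  `effect_size = 0` recovers the uniform design.
- `simulate_monocultures()` shuffles one template count vector (97%
  dominant OTU, 115 OTUs by default) uniformly per sample and swaps the
  maximal count into one of three group-defining OTUs: three groups of
  near-monocultures with identical count multisets.
- `simulate_longbranch_flip()` builds the minimal two-sample instance of
  rarefaction instability: a rare OTU (5 counts out of 1075) on a branch at
  least 5 times the median length, chosen so the exact hypergeometric
  probability of rarefying it to zero lies strictly inside (0.2, 0.8) —
  i.e. the OTU's presence is genuinely bistable across instances.

What these generators do **not** emulate: sequencing error, chimeras,
overdispersion between biological replicates (all uniform samples share
literally the same composition, which real single-site surveys do not), or
any real taxonomy. Passing tests on them demonstrates the metrics'
mechanistic behaviours — presence-flip sensitivity, extreme-abundance
muting, geometric-mean centering — not performance on any particular real
survey, and the variance-explained percentages seen on real data are out of
reach by design.

## Problem sizes and numerical choices

The packaged experiments run at desk scale as a deliberate choice: the
stability comparison uses 60 samples × 554 OTUs × 100 rarefactions (about
ten seconds), the monoculture analysis 60 samples × 115 OTUs, and the
oracle-equivalence checks 100 random trees of up to 10 leaves against
literal subtree-enumeration implementations at 1e-10. Other conventions:
proportions must close to 1 within 1e-8; distance matrices are symmetrized
exactly and clamped at zero against float jitter; PCoA drops eigenvalues
below a 1e-10 relative tolerance; degenerate ordinations (zero pooled PC1
range) are an error rather than a NaN; and the confidence ellipse flags a
singular covariance (collinear points) instead of inventing an axis.

## Known limitations

- Ratio UniFrac's values depend on the zero-replacement pseudocount; only
  the default (0.5) is exercised by the packaged experiments.
- The stability diagnostic aligns the first two PCoA axes. When the first
  two eigenvalues are nearly tied, PC1 identity itself is unstable and
  `V_res` conflates axis swapping with genuine sample movement; this is a
  property of the quantity, faithfully reproduced, not a numerical issue.
- Generalized UniFrac's interpolation family, permutation significance
  tests, and PERMANOVA are out of scope.
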