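---
title: "Two-step clustering of dynamic functional network connectivity"
author: "DFNCluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step clustering of dynamic functional network connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DFNCluster)
```

## The model

Resting-state fMRI component time courses (one column per intrinsic
connectivity network) are summarized, in each tapered sliding window, by
the matrix of pairwise Pearson correlations. With $C$ components a window
yields $F = C(C-1)/2$ distinct connectivity features; stacking the $T$
windows of one subject gives the subject's dFNC tensor, a $T \times F$
matrix. Recurring whole-brain connectivity patterns ("dFNC states") are
the centroids of a k-means clustering of these windowed connectivity
vectors under the within-cluster sum-of-squares objective

$$\min_{\mu_1,\dots,\mu_k} \sum_{j=1}^{k} \sum_{x_i \in C_j} \lVert x_i - \mu_j \rVert^2 .$$

The conventional analysis pools every subject's windows, selects the
number of states $K$ by an elbow criterion, fits one k-means at $K$, and
reads off each subject's *state vector* (the per-window nearest-state
labels). Pooling is exactly what stops scaling: the whole collection must
sit in memory for the elbow sweep and the final fit.

The two-step procedure avoids that. Subjects are split into disjoint
batches of $m$; for each batch a k-means sweep is run at every order
$k = 2, \dots, L$, and all the resulting centroids are kept. A full batch
contributes $\sum_{k=2}^{L} k = L(L+1)/2 - 1$ centroids, so $r = n/m$
batches leave $r\,(L(L+1)/2 - 1)$ rows — a drastically reduced stand-in
for the full window collection. The elbow criterion and a second k-means
are then run on this aggregate, and every subject's windows are assigned
to the final centroids exactly as in the conventional pipeline. Only one
batch of tensors is ever materialized at a time (`runTwoStep` accepts a
store directory and loads subjects lazily), which is the method's point.

## Windowing choices

The window is a rectangle of `length` samples convolved with a unit-area
Gaussian of standard deviation `taperSigma` samples, truncated to the
window and rescaled to maximum 1 (`taperWeights`). Defaults are
`length = 30`, `step = 1`, `taperSigma = 3` samples — the prevailing
convention in the sliding-window dFNC literature; all three are
arguments of `windowSpec`. The taper enters as weights of a weighted
Pearson correlation (weighted means, variances and covariance), so unit
weights reduce exactly to the textbook sample correlation rather than
pre-multiplying the signals. Correlations are clamped to $[-1, 1]$
against rounding; a Fisher z-transform is available behind
`fisherZ = TRUE` and off by default.

A window in which some component is constant has no defined correlation.
Such windows raise an error naming the subject, window and component —
silent `NaN`s would poison the clustering downstream.

## Model-order selection

The elbow criterion the dFNC literature invokes has no canonical
formula, so `elbowSelect` makes the choice explicit and configurable:

* `curvature` (default): the inertia curve is anchored at the
  closed-form $k = 1$ point (the total sum of squares) and the selected
  $k$ maximizes the second difference of **log** inertia — equivalently,
  the ratio of successive inertia drops. Two properties motivated this.
  First, the anchor: any geometric construction on the swept points
  alone assigns the endpoints zero salience, so an elbow at the lower
  end of the range would be structurally unselectable without $k = 1$.
  Second, the log scale: it makes the selection invariant to the overall
  inertia scale. The linear second difference inherits the magnitude of
  the $k=1\!\to\!2$ drop and prefers $k = 2$ even on data with three
  well-separated masses; on the log curve the three-mass case selects 3
  and two-state data selects 2, both with wide margins.
* `chord_distance`: the classical kneedle-style rule — normalize the
  anchored $(k, \text{inertia})$ points to the unit square and take the
  $k$ farthest from the chord joining the endpoints (`chordElbow`
  implements the geometry). On curves with a dominant first drop
  followed by a secondary one, the chord distances of adjacent
  candidates differ only in the third decimal, so the choice is decided
  by optimizer noise; this fragility is why it is not the default.
* `wcss_ratio`: mean within-cluster distance over mean between-centroid
  distance, the convention of the GIFT-style dFNC toolchain, with the
  bend located by the chord geometry.

Ties always go to the smaller $k$ (parsimony).

## Temporal features and quality

From each state vector the package computes the occupancy rate (fraction
of windows per state; sums to one, reported as fractions rather than
percentages so the invariant is clean) and the number of between-state
transitions (adjacent-window label changes, in $[0, T-1]$). Mean dwell
time is deliberately not computed — occupancy and transitions are the
two features the analysis tracks.

Clustering quality per subject is the mean over windows of
$d_{i\_sc}/d_{i\_c}$, where $d_{i\_c}$ is the Euclidean distance of
window $i$ to its own centroid and $d_{i\_sc}$ the **sum** of distances
to the other $K - 1$ centroids. The ratio therefore scales with $K - 1$:
only models with equal $K$ are compared. Own-centroid distances below
$10^{-12}$ are floored there (and logged) instead of dividing by zero.
Cross-pipeline quality is compared with a two-sample t-test, Welch by
default (`varEqual = TRUE` gives the pooled form) — no equal-variance
assumption is warranted between pipelines.

State models are compared by matching their centroids one-to-one with an
optimal assignment (an in-package Hungarian solver) maximizing the
summed Pearson correlation of paired centroid vectors; "matched-state
similarity" is the minimum (and mean) correlation over matched pairs.
For $K \le 4$ the solver is verified against exhaustive permutation in
the tests.

## The synthetic generator

`defaultFixture` emulates the statistical structure the clustering
assumes: a hidden Markov chain over $K$ covariance regimes, each regime
drawing timepoints i.i.d. from a multivariate normal. Defaults, chosen
once as the package's study conditions: $C = 10$ components,
$T_{\text{total}} = 400$ timepoints, two states (one 5-component block
at $r = 0.6$; the complementary block at $r = 0.6$ with cross-block
$r = -0.3$ — nearly orthogonal in feature space, pairwise $r < 0.3$),
symmetric transitions with stay probability 0.98, and a dwell-time floor
of 40 timepoints so that windows (30 samples) are dominated by single
states. The floor is enforced by letting each entered state persist 40
steps before the next transition draw; the dwell beyond the floor is
geometric in the leave probability. Means are zero — correlations are
location-invariant, so nonzero means would add nothing.

What the generator does **not** emulate: autocorrelated BOLD dynamics
within a regime (draws are i.i.d. in time), gradual state transitions,
subject-level covariance heterogeneity, scanner noise and motion
artifacts, and the $C = 53$, $n$-in-the-hundreds scale of real cohorts.
Passing tests therefore show that the pipeline recovers planted
covariance structure under its own model assumptions at desk scale, not
that it is robust to the full messiness of rs-fMRI.

One desk-scale effect deserves note: with mean dwell near 90 timepoints,
roughly a third of 30-sample windows straddle a state change. These
mixed windows blur the two planted clusters, which is what makes the
model-order curves less crisp here than on long-dwell data — and is
precisely why the scale-invariant curvature rule above earns its place.

## Numerical choices

* k-means: Lloyd iterations from k-means++ seeding, best of
  `nInit = 10` restarts by inertia, `maxIter = 300`, convergence when
  the relative inertia change falls below `tol = 1e-4`. Deterministic
  given a seed; assignment ties go to the lowest centroid index; an
  emptied cluster is re-seeded at the point farthest from its centroid.
  Squared Euclidean distance throughout, directly from the objective; a
  city-block variant (medians) is available via `distance = "manhattan"`
  but is not the default since the printed objective is sum-of-squares.
* Second clustering step: each aggregated centroid counts once,
  mirroring the aggregate's role as plain observations. A
  size-weighted variant (`weightBySize = TRUE`) weights each centroid by
  its source-cluster size; it brings the single-batch ($m = n$) limit of
  the two-step pipeline into near-exact agreement with the conventional
  one (matched correlation > 0.99, vs ≈ 0.97 unweighted at desk scale).
* Remainder subjects when $m \nmid n$ are appended to the final batch:
  subjects are exhausted, never dropped.
* Final states are re-indexed by descending total occupancy across
  subjects (ties to the lower original index), so state 1 is always the
  most visited and numbering is comparable across runs and pipelines.
  Labels are 1-based, following R convention.
* Tensor storage is a directory container: `meta.json` (schema version,
  feature index, window starts) plus one full-precision (`%.17g`) TSV
  per subject, so stored doubles round-trip exactly and
  `dfncStoreLoader` can materialize one subject at a time.

## Problem sizes

The test-suite and acceptance runs use 20 subjects (8 for the unit
tests), $C = 10$, $T_{\text{total}} = 400$ (371 windows of 45 features
per subject), batches of $m = 2$ and $m = 1$ with $L = 6$, an elbow
range of 2–8, and ensembles of 5 seeds — sizes at which the full
two-pipeline comparison runs in well under a minute per seed while
keeping the planted-recovery margins interpretable.

## Known limitations

* The two-step aggregate is a coarse summary at very small $n$: with a
  single batch the second step sees only $L(L+1)/2 - 1$ rows, and
  unweighted averaging of split-cluster centroids biases the final
  states by a few percent (see the size-weighted variant above).
* Transition counts of 20-subject fixtures are small integers, so their
  cross-pipeline correlation is dominated by single boundary-flicker
  subjects; occupancy correlations are the steadier equivalence metric
  at this scale.
* The elbow anchor assumes inertia is meaningful at $k = 1$; on data
  whose total variance is dominated by a single outlying direction the
  anchored curvature can overweight the first drop, and `wcss_ratio`
  may be the better-behaved alternative.
* Wall-clock speedups of the two-step scheme are hardware- and
  scale-dependent and are neither measured nor asserted here; per-stage
  timings are logged for information only.
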