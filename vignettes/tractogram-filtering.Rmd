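---
title: "Bundle-grouped tractogram filtering: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bundle-grouped tractogram filtering: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractfilt)
```

## The problem

Tractography turns a diffusion-MRI orientation field into streamlines —
3D polylines that stand for coherent groups of axons. Modern algorithms
recover essentially all true white-matter bundles, but at the cost of
many false-positive connections, typically created where distinct fiber
populations cross: the tracking algorithm switches from one bundle to
another mid-course and emerges connecting a pair of gray-matter regions
that share no anatomical connection. Because a structural connectome edge
exists as soon as *any* streamline connects a region pair, low
specificity is the dominant failure mode of connectome mapping.

`tractfilt` treats filtering as an inverse problem with an anatomical
prior. Two observations drive the model:

1. **Streamlines are not just lines.** Each represents a population of
   axons occupying physical volume, so its contribution to a voxel must
   be proportional to its length inside that voxel, and the total
   streamline volume in a voxel must sum to the measured intra-axonal
   signal fraction there.
2. **Axons are organized in bundles.** Streamlines connecting the same
   pair of gray-matter regions form one anatomical unit and should be
   kept or removed together.

## Forward model

For a grid of $n_v$ voxels and a tractogram of $n_c$ streamlines, the
operator $A \in \mathbb{R}^{n_v \times n_c}$ has entry
$A_{vj} = \ell_{vj} / V$, where $\ell_{vj}$ is the arc length of
streamline $j$ inside voxel $v$ and $V$ the voxel volume. With
coefficients $x \ge 0$ interpreted as cross-sectional areas (mm²), the
product $A x$ is a dimensionless volume fraction directly comparable to
an intra-axonal signal-fraction map $y$:

$$y = A x + \eta.$$

The choice of area (rather than volume) as the unit for $x$ makes the
fraction constraint dimensionally exact. Lengths are computed by exact
parametric clipping of each polyline segment against the integer voxel
planes; per-voxel lengths sum to the in-grid arc length by construction
(telescoping of the clip parameters), which the tests verify to $10^{-9}$
relative on 1000 random polylines. Voxel boxes are half-open with points
on a face belonging to the higher-index voxel — a deterministic
tie-break. Degenerate zero-length streamlines map to an empty traversal;
a streamline with no in-grid voxel would create a zero column and is
rejected by name.

A second operator mode serves the didactic four-voxel instance: rows are
(voxel, gradient-direction) pairs, a streamline contributes a "stick"
signal $\exp(-b\, d_\parallel (g^\top u)^2)$ along its local direction
$u$ in each traversed voxel, and each voxel owns one isotropic "ball"
column $\exp(-b\, d_{\mathrm{iso}})$ for CSF-like water. Defaults are
$b = 3000\ \mathrm{s/mm^2}$, $d_\parallel = 1.7\times10^{-3}$,
$d_{\mathrm{iso}} = 3.0\times10^{-3}\ \mathrm{mm^2/s}$, 30 quasi-uniform
directions: recovery of the toy coefficients is invariant to these
constants as long as the 7 columns remain identifiable, which requires
at least 7 directions (enforced) and generic orientations (a seeded
random rotation of a Fibonacci hemisphere lattice).

## Estimation

The unregularized fit is non-negative least squares,
$\min_{x \ge 0} \lVert Ax - y \rVert_2^2$. The anatomical prior enters
as an adaptive group lasso over the partition $G$ of streamlines into
ROI-pair bundles:

$$\min_{x \ge 0}\; \lVert Ax - y\rVert_2^2
  + \sum_{g \in G} \lambda^{(g)} \lVert x^{(g)} \rVert_2,
  \qquad \lambda^{(g)} = \lambda\, \frac{|g|}{\lVert x^{(g)}_{\mathrm{NNLS}}\rVert_2}.$$

The weight normalizes each group's penalty by how strongly the
unregularized fit supports it: numerous-but-weak groups (the false
positive signature) get large penalties and are zeroed as blocks;
$\lambda = 0$ recovers NNLS. Groups whose NNLS norm is numerically zero
receive an infinite-weight sentinel and are fixed at zero — the adaptive
weight is undefined there and the data already rejected them. A
`sqrt_cardinality` variant ($\sqrt{|g|}$ in the numerator, the scaling
under which penalties are cardinality-neutral for equally supported
groups) is available but not the default; the default follows the
adaptive weight as commonly printed, proportional to $|g|$.

### Solver

All problems are solved by one accelerated proximal-gradient (FISTA)
routine:

* **Exact prox.** The proximal map of
  $t\lVert\cdot\rVert_2 + \iota_{\ge 0}$ is projection onto the
  non-negative orthant followed by block soft-thresholding; feasibility
  ($x \ge 0$) is therefore exact at every iterate, and inactive groups
  are exactly zero rather than small.
* **Step size.** $1/L$ with $L = 2\sigma_{\max}(A)^2$ from a
  deterministic power iteration; underestimates are caught by halving
  backtracking against the quadratic majorizer.
* **Monotonicity.** On an objective increase the momentum is restarted
  and a plain proximal step taken, so the recorded objective trace is
  non-increasing (a property the tests assert).
* **Preconditioning.** Columns are rescaled to comparable norms before
  solving — individually for unpenalized columns, with a single shared
  factor per group for penalized ones, so the group penalty transforms
  exactly ($w_g \mapsto w_g / d_g$) and the objective value is
  unchanged. This matters: the ball columns of the toy instance have
  norms $\sim 10^{-4}$ of the stick columns, and without equilibration
  first-order methods stall on that axis.
* **Stopping.** Relative objective change below `tol` ($10^{-8}$ by
  default, far tighter than any effect measured) or `max_iter` (2000).
  Tests that assert coefficient-level recovery use `tol = 1e-12` or
  tighter.
* **Warm starts.** `lambda_sweep()` reuses the previous solution along
  an ascending grid; cold-start spot checks in the tests confirm the
  warm-started optima.

Correctness is established against independent oracles: the closed-form
prox against a constrained quadratic program solved by projected
L-BFGS-B on a smoothed surrogate; the FISTA NNLS against Lawson–Hanson
active-set NNLS (`pracma::lsqnonneg`); the group lasso at $\lambda = 0$
against NNLS; and KKT stationarity residuals at convergence.

### Pipeline conventions

Endpoints are assigned to the nearest labeled voxel *center* within 2 mm
(Euclidean, world space); the radius is configurable, the center-based
distance is a stated choice (boundary distance or label dilation would
be alternatives; at 1 mm voxels they differ by at most half a voxel
diagonal). Distance ties go to the lower label — deterministic. A
streamline is kept only if both endpoints assign to two *distinct* ROIs;
self-connections are excluded because a bundle is defined between
distinct regions. Unassignable streamlines are dropped *before* fitting
(their count is reported): this keeps the groups a true partition of the
fitted columns, and the connectivity analysis excludes them regardless.
Filtered edges with total weight below $10^{-12}$ are treated as absent
(solver floating-point noise).

## Evaluation

Against a ground-truth connectome: VB (estimated edges present in the
truth), IB (absent), VC/IC (streamline-count ratios), sensitivity
$VB/P$, specificity $1 - IB/N$, Youden's $J$, and max-normalized
connectome errors

$$\varepsilon = \sqrt{\textstyle\sum_{i<j} (C_{ij} - \tilde C_{ij})^2},$$

summed over the upper triangle by default so each unordered pair counts
once (for symmetric matrices the full-matrix sum, available via
`full = TRUE`, is exactly $\sqrt 2$ larger — the convention is a
documented switch, not a hidden constant). $\varepsilon_{TP}$ restricts
the sum to true-positive positions. An all-zero estimate skips its own
normalization and is compared as zeros.

$P$ is the phantom's true bundle count. $N$ — the specificity
denominator — is the number of *reachable* negatives: ROI pairs the
candidate generator can connect by splicing true bundles at crossings
(`reachable_negatives()`), mirroring the idea that real negatives are
the pairs an exhaustive permissive tracking run could connect
incorrectly, not all label pairs.

Two baselines frame the comparison: cardinality thresholding (drop edges
with $\le k$ streamlines, swept over $k$) and random bundle removal at a
matched removal rate (mean $J$ over repeated draws, seeded; its
expectation has the closed form
$(1-r)\,VB/P + 1 - (1-r)\,IB/N - 1$ with $r$ the realized removal
fraction, which the tests verify by Monte Carlo).

## The phantom generator

`make_phantom()` emulates the study conditions of a digital connectivity
phantom: ROIs as spherical caps (default radius 2.5 mm) on a sphere
inscribed in a $30^3$ 1 mm grid, laid out on a seeded rotation of a
Fibonacci lattice and rejection-sampled until disjoint (failure is
explicit, naming the constraint); bundle centerlines as natural cubic
splines (third-order piecewise polynomials) between ROI centers with a
random interior control point pulled toward the grid center so bundles
cross centrally; bundle radii uniform in 1.5–4 mm; fibers tiling each
bundle's cross-section on a sunflower lattice, tapered to the ROI
centers at both ends so endpoints always assign correctly. The fraction
map is computed *from the ground-truth fiber geometry* through the same
length operator used in fitting, then map and per-fiber areas are
rescaled together so the map peaks at 0.5 (a mid-range intra-axonal
fraction): the identity `map == A %*% areas` is exact by construction,
which is what makes noiseless parameter recovery a meaningful test
(relative error $\le 10^{-4}$ is asserted; the observed error is orders
tighter). The standalone `compute_fraction_map()` clips at a cap of 1
with a warning instead, since arbitrary user tractograms can oversubscribe
a voxel.

`generate_candidate_tractogram()` emulates what tractography would
return: jittered true streamlines (uniform cross-section offsets,
smooth low-frequency jitter of 0.2 mm) plus false bundles built by
splicing two true centerlines at a shared crossing voxel and re-smoothing
— reproducing the crossing-switch mechanism rather than arbitrary random
walks. False-bundle cardinalities may be set per bundle; the reference
fixture uses 5 true bundles of 15 streamlines against false bundles of
(20, 10, 8, 6), deliberately overlapping the true cardinalities so that
no count threshold can separate them cleanly — the regime where grouping
matters.

What the generator does *not* emulate: DW-signal synthesis and Rician
acquisition noise (the fitted quantity here is the fraction map, whose
noise model is not specified by the phantom literature; optional
Gaussian noise on the map is available and off by default), partial
voluming with an extra-axonal compartment, curved-sheet anatomy, or the
streamline-count imbalances of real seeding strategies. Passing tests on
this phantom therefore demonstrate the estimator's behavior under its
own model assumptions — correct bundle selection when the data are
explainable by the true geometry — not robustness to model mismatch on
in vivo data.

## Problem sizes and runtime envelope

The test fixtures are chosen at desk scale: a $30^3$ grid, 10 ROIs, 5
true + 4 false bundles, 119 candidate streamlines, a 20-point
logarithmic $\lambda$ grid in $[10^{-4}, 10]$ (chosen a priori to span
from no-effect to full saturation of the penalty). A full sweep runs in
seconds; the complete test suite in about half a minute. The
implementation is pure R on `Matrix` sparse types and scales linearly in
stored entries per iteration, but it is not engineered for
million-streamline whole-brain tractograms — that regime needs
compiled kernels and is out of scope here.

## Known limitations

* Only the intra-axonal and (optional) isotropic compartments are
  modeled; no extra-axonal/hindered block.
* TCK is the only tractogram format (world-mm coordinates, MRtrix
  dialect); no TRK support.
* All NIfTI inputs must share one grid; the package never resamples.
* The $\lambda$ grid is the user's choice; no information criterion is
  provided for selecting a single $\lambda$ without ground truth.
* Endpoint assignment is volumetric (voxel-center distances); surface
  parcellations are not supported.
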