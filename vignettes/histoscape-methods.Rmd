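---
title: "histoscape: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{histoscape: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoscape)
```

`histoscape` treats a classified histology image as a categorical
landscape and annotated tissue features as spatial point patterns, and
quantifies both with methods from landscape ecology and spatial
statistics. This vignette is the package's account of those methods:
what is computed, under which conventions and assumptions, which
defaults were chosen where the design was genuinely open, and what the
synthetic test conditions do and do not demonstrate.

## Coordinate and raster conventions

One convention is used everywhere. A raster pixel `(row, col)`
(1-based, row 1 at the top) has centre `(x = col − 0.5, y = row − 0.5)`
in units of `resolution` (default 1 pixel); the image spans the window
`[0, ncol] × [0, nrow]` with y increasing downward. ImageJ ROI
coordinates (0-based integer pixels) convert by adding 0.5. Polar
angles undo the raster y-flip so that "up in the image" is 90° and the
orientation is the standard mathematical one; `flip_y = FALSE` is
available for data already in mathematical orientation.

Patch detection defaults to 8-connectivity, with 4-connectivity as a
flag. The reference tool family this framework mirrors does not state
its connectivity; 8 is those tools' usual default, and every patch
metric is well defined under either choice. Adjacency counting, by
contrast, is fixed at the 4-neighbour double-count convention (each
unordered pixel edge contributes one ordered pair in each direction),
because the aggregation, contagion and complexity formulas are defined
on exactly that matrix. Pairs touching nodata are dropped; patches
never cross nodata; nodata pixels are excluded from every metric.

## Landscape metrics

Patch level: area (pixels × resolution²), perimeter (boundary cell
edges × resolution, counting edges against nodata and the image
border), shape index `0.25·perimeter/√area` (1 for a square), and
Euclidean nearest-neighbour distance to the closest same-class patch
(edge-to-edge over boundary pixel centres; `NA`-flagged when the class
has a single patch — flagged, never silently zero, so the ML filter can
drop it).

Class level: PLAND, patch count and density, largest patch index, total
edge and edge density (boundary edges of the class's pixels), mean
patch area, and the aggregation index `AI = 100 · g_ii / max g_ii`,
where `g_ii` counts like adjacencies once and `max g_ii` uses the
standard largest-integer-square construction; a single-pixel class has
`max g_ii = 0` and AI is flagged undefined.

Landscape level: patch count, inter-class total edge and edge density,
mean patch area, largest patch index, Shannon diversity
`SHDI = −Σ pᵢ ln pᵢ`, Shannon evenness `SHDI / ln m` (undefined for
m = 1), Simpson diversity `1 − Σ pᵢ²`, the area-weighted mean of the
class AIs, and contagion in its adjacency-probability form, normalised
by `2 ln m` (undefined for m = 1). "The complete metric suite" of the
source tools is an open-ended catalogue; the package implements the
groups that feed its downstream clustering and classification —
aggregation, area-and-edge, diversity, complexity — and the long-table
schema (`case_id, level, id, metric, value`) admits new metrics without
breaking stored tables.

The four complexity metrics are computed in bits from the normalised
co-occurrence distribution: marginal entropy of the row-marginal class
distribution, joint entropy, conditional = joint − marginal, mutual
information = marginal − conditional, and relative mutual information
MI/marginal (undefined for a single-class landscape). The identities
`joint = marginal + conditional` and `0 ≤ MI ≤ marginal` are enforced
by construction and by tests.

## Point-pattern estimators

Windows are axis-aligned rectangles only — the framework's use case
crops the largest rectangle common to an image set — and polygonal
windows are out of scope.

Ripley's K uses the standard estimator
`K̂(r) = |W|/(n(n−1)) Σ_{i≠j} e_ij 1[d_ij ≤ r]`. Corrections: `none`
(`e = 1`); `translation` (`e_ij = |W|/((a−|dx|)(b−|dy|))`, the default,
valid in any rectangle); `isotropic` (Ripley's circle-fraction weight in
its closed rectangular form, truncated with a warning at half the
shorter side, where the weight becomes unstable); `border` (reduced
sample). `L = √(K/π)`, with the centred `L(r) − r` form for plotting
against CSR. The default r-grid is 512 points from 0 to a quarter of
the shorter window side.

G is the empirical CDF of nearest-neighbour distances and F the
empirical CDF of empty-space distances evaluated on a regular lattice
of test locations with spacing `min(side)/128` (configurable).
Default edge correction is reduced-sample (border): at distance r only
points/test locations at least r from the boundary contribute. It is
the simplest estimator to verify against brute-force enumeration, which
is why it is the default; the Kaplan–Meier estimator (boundary distance
as censoring time, via the survival package) is available by flag.
`J = (1−G)/(1−F)` is reported only where `F < 1`; note that J is a
ratio of estimates and becomes numerically wild as F approaches 1, so
calibration checks read it over the informative range of r only.

Envelopes simulate CSR conditionally on the observed n (a binomial
process) in the same window, with the same estimator and correction as
the empirical curve. Pointwise envelopes are rank envelopes: with
`n_sim = 99` at α = 0.05, the 3rd-lowest and 3rd-highest simulated
values per r. Global envelopes are maximum-deviation bands around the
simulation mean, with the critical deviation the
`⌈(1−α)(n_sim+1)⌉`-th smallest simulated maximum absolute deviation.

The studentized permutation test for grouped patterns reduces each
pattern to its summary function on a common r-grid and uses
`T = Σ_{i<j} ∫ (f̄ᵢ − f̄ⱼ)² / (sᵢ²/mᵢ + sⱼ²/mⱼ) dr` (trapezoid
quadrature; the between-pattern variance is floored at 1e−12 so
identical patterns yield T = 0 rather than 0/0). The p-value permutes
pattern-to-group labels with the add-one convention
`p = (1 + #{T* ≥ T})/(1 + n_permutations)`, so p is never exactly 0.
Because the aggregation of such tests across several summary functions
is not uniquely defined, the package exposes per-function tests and a
clearly labelled sum-over-functions variant
(`combined_permutation_test`), without claiming equivalence between
the two.

Voronoi cells are computed by clipping the window with
perpendicular-bisector half-planes (Sutherland–Hodgman), so cell areas
sum to the window area by construction; Stienen circles have diameter
equal to each point's nearest-neighbour distance, with
boundary-crossing circles flagged for the conventional "not plotted"
treatment.

All Monte-Carlo operations take an explicit integer seed and restore
the caller's RNG state; identical seeds give bit-identical results.

## Lobule model and scar-axis analysis

The lobule model idealises the hepatic lobule as a regular hexagon:
central vein at the centre, portal tracts at the vertices. Per central
vein, the mean r of the distances to the 6 nearest portal tracts is the
circumradius estimate and the lobule area is `(3√3/2)·r²`. The model
is exact on an unjittered honeycomb and degrades gracefully with
annotation noise; estimates are emitted per vein, so two-group
comparisons can be run either on per-vein areas or on per-case means —
both sampling units are legitimate, the tests in this package use
per-vein areas and say so.

Scar-axis analysis takes myofibroblast (MFB) nuclei and the annotated
central-vein circumference. Distances d are shortest point-to-segment
distances to the ring — the circumference, deliberately not the
centroid. Angles ϕ are polar angles about the ring's shoelace
centroid. The angular density is a wrapped (circular) Gaussian KDE on a
1° grid integrating to 1 over the circle; a linear KDE would split mass
across the 0°/360° seam and can misplace the peak when the dominant
axis lies near the seam, which is why the circular estimator is used.
Bandwidth is Silverman's rule on the angle sample, configurable.
Alignment shifts all angles by `(90° − ϕ_peak)`, preserving pairwise
angular differences and all radial distances (for a non-circular ring
this is an angular relabelling, not a re-measurement of d).

The axial sine fit `A·sin(2πϕ/P + φ₀) + C` deliberately leaves the
period P free — bipolarity is then a finding the fit can recover (P
near 180°), not an assumption baked in. The optimiser is
Levenberg–Marquardt multi-started from period seeds 360°, 180° and
120°, each warm-started by the linear least-squares solution at that
fixed period; the best-RSS fit is returned with amplitude normalised
non-negative. A constant density returns zero amplitude with the
period flagged unidentifiable. Radial densities use a Gaussian KDE
reflected at zero and renormalised on `[0, max d]`, since distances
cannot be negative. Aggregation across fields, where wanted, pools
cells; per-field summaries are available by mapping over fields — both
are labelled by the caller rather than silently mixed.

Two-group comparisons use Welch's unequal-variance t-test
(`stats::t.test`) for near-normal summaries and a bootstrap
Kolmogorov–Smirnov test for distributions: D is the tie-tolerant
sup-difference of empirical CDFs and the p-value resamples both groups
from the pooled sample with the add-one convention.

## Feature pipeline and classification

Features are the landscape-level, class-level and complexity metrics of
each image, flattened to one row per case region. Splitting is by case
id — paired lesional/non-lesional regions of one case never straddle
the train/test boundary — and stratified by the case-level label
profile; this is stricter than an unconstrained random split, and
deliberately so, because region pairs from one case are not independent.

Filtering is fitted on training rows only: (1) drop features undefined
anywhere or with near-zero variance (most-common/second-most-common
frequency ratio > 19 and unique fraction < 10%); (2) a rank-based
inverse-normal transform per feature — "optimal normalisation" is
under-specified as a method name, and the rank-based transform is a
robust, parameter-free stand-in whose provenance is recorded in the
fitted transform object; (3) a greedy correlation filter removing one
member of each pair with |r| > 0.75 (the member with the larger mean
absolute correlation; ties resolved by column order). The fitted
transform is reapplied to test data by interpolating the training
rank-to-score mapping, never refitted; a test asserts the fitted object
is byte-identical under arbitrary mutation of test rows.

The classifier is a random forest (√p candidate features per split)
with a 10,000-tree default, configurable down for tests (the test suite
uses 150–500 trees with fixed seeds). Evaluation sweeps the predicted
positive-class probability over all distinct thresholds: ROC, trapezoid
AUC, F1 per threshold and the F1-maximising threshold. Variable
importance combines the forest's out-of-bag permutation accuracy
decrease and Gini decrease with structure measures recomputed from the
stored trees: mean minimal depth (trees not containing a feature
contribute that tree's maximal depth + 1), split-node and root counts,
and a one-sided binomial p-value for the node count against
uniform-random split-variable choice — an approximation, since the
null ignores per-split candidate subsampling. Pairwise interaction
importance is simplified to parent–child split co-occurrence counts
within trees; full conditional-importance machinery is out of scope.
Case clustering standardises features and runs Lloyd's k-means with 10
restarts.

## Synthetic study conditions

The generators emulate the framework's inputs with controllable ground
truth; they are a test harness, not a model of biology.

* `gen_clumpy_raster` smooths an iid Gaussian field with a separable
  Gaussian kernel (sd = clumpiness × min(shape)/8 pixels) and
  thresholds at class-weight quantiles. It produces ordered,
  blob-like class mosaics whose edge density falls and aggregation
  rises monotonically with clumpiness — sufficient to drive the metric
  and classification tests — but it is not the modified-random-clusters
  algorithm and does not imitate stain texture, anisotropy or
  structured tissue boundaries.
* `gen_point_process` provides homogeneous Poisson (CSR), Matérn
  cluster (parents in the R-dilated window) and simple sequential
  inhibition processes.
* `gen_lobular_lattice` puts central veins on a triangular lattice of
  spacing s and portal tracts at the shared honeycomb vertices
  (circumradius s/√3, true lobule area (√3/2)s²), with iid Gaussian
  jitter; centrals are kept only where their full vertex ring fits in
  the window so the unjittered lattice is recovered exactly.
* `gen_scar_field` draws MFB angles from a two-component
  wrapped-normal axial mixture at θ* and θ* + 180° (weights w ≥ 0.5 and
  1 − w, angular sd 1/√κ radians; κ = 0 gives uniform angles) and
  ring distances from an exponential with rate `radial_decay`. The
  antipodal-spur geometry is an observed phenotype being emulated, not
  a mechanistic claim.

Default study conditions used by the acceptance checks: 20 seeded CSR
patterns of expected n = 500 (indices) or n = 150–200 (functions) in
the unit square; 20 seeds per direction-of-effect arm; lobule lattices
of spacing 100 with 5% jitter and 10 lobules per group for the
enlargement test; scar fields of 500 cells at κ = 20, w = 0.7; and for
the classification arms 150 paired-region cases per arm of 64×64
three-class rasters at clumpiness 0.65 vs 0.35 (signal) or 0.5 vs 0.5
(null), 500 trees. These sizes make the whole suite run comfortably on
a single CPU while leaving each statistical check well powered; they
are stated here so the numbers in `scripts/acceptance.R` output are
interpretable as estimates under exactly these conditions.

Passing these checks shows the estimators are calibrated and the
pipeline recovers planted structure under the generators' assumptions
(stationarity, rectangular windows, iid noise). It does not show
robustness to the things real histology adds: inhomogeneous intensity,
segmentation artefacts, anisotropy, irregular tissue boundaries, or
batch effects between slides.

## Degenerate inputs and numerical policy

Empty rasters, all-nodata masks, single-pixel landscapes (zero
adjacency), patterns with n < 2, groups with fewer than 2 patterns,
fewer than 6 portal tracts, degenerate rings and coincident points all
raise informative errors or, where a convention exists (vertex-mean
centroid fallback, undefined-metric flags, unreachable inhibition
targets), warn and proceed. Undefined metric values are always `NA`,
never 0. Proportions sum to 1 within 1e−12; Voronoi areas to the
window area within 1e−6 relative; the entropy identity holds within
1e−9. Known limitations: no inhomogeneous-intensity function variants
(K_inhom etc.), no marked correlation functions, no point-process model
fitting, no polygonal windows, no whole-slide tiling, and no pixel
classification — the framework is classifier-agnostic by design and
starts from the label map.
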