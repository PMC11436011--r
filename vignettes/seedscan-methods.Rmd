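---
title: "Methods: from table scans to seed shape models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from table scans to seed shape models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscan)
```

This vignette explains the models and algorithms behind `seedscan`, the
assumptions they rest on, the tunable parameters and their defaults, and
what the synthetic test bed does and does not demonstrate about real
scanner data.

## Setting and assumptions

A batch scan delivers one cloud (mm coordinates) containing a table plane
and many seeds. Three physical facts drive the design:

* **seeds rest on the table**, so the table-facing side of every seed is
  unobserved — roughly an angular cap around the downward direction;
* **seeds are rigid and their cross-sectional profiles are approximately
  elliptical**, which is what makes principled completion of the missing
  cap possible without a learned shape prior;
* **seeds are star-shaped about their centroid** (no handles, no deep
  concavities), which the surface reconstruction exploits.

Heavily overlapping or pasted seeds are out of scope: region growing
cannot split surfaces that merge smoothly into one another.

## Segmentation

`removeTableRansac()` detects the single best plane by RANSAC (1000
iterations, reproducible sampling with a fixed default seed) and removes
points within **0.05 mm** of it. On scenes larger than 30k points,
candidate planes are scored on a 30k subsample and the winner is refined
twice by a total-least-squares fit to its inliers before the final inlier
test on the full cloud. If no plane reaches 20 % support the scene is
returned unchanged with a warning — the caller may be looking at a
pre-segmented cloud.

`regionGrow()` estimates per-point normals and surface-variation
curvature λ₃/(λ₁+λ₂+λ₃) from 30-nearest-neighbour covariances and grows
clusters from low-curvature seed points: a neighbour joins when its normal
is within the **smoothness threshold of 15°** of the current point's
normal, and continues the front when its curvature is below **0.4**. The
smoothness default follows the conventional region-growing range;
a threshold near 150° would accept every neighbour and reduce the
algorithm to connected components, which defeats the purpose of the
criterion. Both thresholds are arguments.

Cluster filtering uses the covariance-eigenvalue dimensionality features
a₁D = (λ₁−λ₂)/λ₁, a₂D = (λ₂−λ₃)/λ₁, a₃D = λ₃/λ₁ — an exact partition of
unity — with the arg-max rule and the deterministic tie-break
volumetric > planar > linear. Planar clusters (table-edge remnants) are
discarded. One caveat documented here deliberately: a strongly *elongated*
ellipsoidal shell (axis ratio beyond about √2) has a₁D maximal and
classifies as linear under the arg-max rule. Bean-like seeds are round
enough that this never triggers, and `extractSeeds(keep =)` can be widened
to `c("volumetric", "linear")` for elongated material.

## Pose normalization

PCA of the point covariance maps the eigenvectors, in descending
eigenvalue order, to length → X, width → Z, thickness → Y (the ordering
that makes L ≥ W ≥ T hold by construction in the bounding box). Two
conventions remove the inherent PCA ambiguities: each eigenvector's sign
is chosen so the coordinate skewness along it is non-negative (first
non-zero component positive as fallback for symmetric clouds), and the
rotation is made proper (det = +1) by flipping the thickness axis if
necessary. Pose normalization is idempotent and rotation-invariant up to
these sign conventions, which the tests assert explicitly.

## Completion

The pose-normalized cloud is partitioned into **20 equal-width slabs**
along X. Slabs with fewer than 10 points are merged into their nearest
non-empty neighbour before fitting: 6 points is the algebraic minimum for
a conic, and a small margin guards conditioning.

Each slab's (y, z) projection is fitted with the direct least-squares
ellipse method: minimize the algebraic distance of the implicit conic
subject to 4ac − b² = 1, solved via the stable block-partitioned
generalized eigensystem on centred, RMS-scaled coordinates. The constraint
makes the solution ellipse-specific — even a partial arc with noise
returns an ellipse — which is exactly the robustness the occluded-bottom
geometry needs. The returned conic is rescaled so the constraint holds to
machine precision, making coefficients comparable across slabs.

Gap detection is angular: the polar angles of the slab's points around the
fitted ellipse centre are binned into **72 bins of 5°**; a bin with no
scanned point is empty. Finer bins fragment sparse slices, coarser bins
under-fill. The fitted ellipse is sampled inside the empty bins at the
cloud's own density (reciprocal of the median nearest-neighbour spacing by
default), and the samples are laid out in layers across the slab's actual
x-range at that same density. Spreading the fill across the slab — rather
than collapsing it onto a single ring at the slab's mean x — keeps the
filled patch at the same surface density as the scanned points, so the
nearest-neighbour completion error of the fill is commensurate with the
scan rather than dominated by ring spacing. Original points are never
moved or dropped by completion.

The optional Gaussian filter (`gaussianSmooth()`) replaces each point by
the Gaussian-weighted mean of its neighbours within radius = 3× median
spacing (σ = radius/2). At scanner-like densities (0.1 mm) the radial
shrink bias this introduces on a sphere is below 0.005 mm; at the coarser
densities used in desk-scale scenes it grows quadratically with the
radius, which is why the completion-error measurements in the tests are
taken before smoothing.

**Error metric.** `completionError()` reports E_r, the mean over
ground-truth points of the distance to the nearest completed point,
divided by the truth count. This direction — truth to completed — is the
one under which completion is guaranteed to help (the occluded input has
no points near the missing cap at all); the reversed direction and the
symmetric chamfer mean are available via `direction=`. Note that E_r is a
point-to-*sample* distance: even a geometrically perfect fill cannot beat
the sampling quantization of the reference cloud (≈ 0.35× its spacing),
so "how close is the fill to the true *surface*" is tested separately via
the analytic ellipsoid residual in the test suite.

## Surface reconstruction

No installed mesh library is relied on; the reconstruction is authored
here for the star-shaped case. Directions from the cloud centroid to a
subdivided icosahedron's vertices (level 4: 2562 vertices, 5120 faces, ~4°
resolution) are assigned radii by Gaussian-kernel regression over the k =
12 angularly nearest cloud points, with a per-vertex adaptive bandwidth of
half the k-th neighbour chord. The mesh inherits the icosphere's
topology, so it is closed and consistently oriented *by construction*;
orientation is normalized to positive signed volume. Kernel averaging also
suppresses coordinate noise by ~1/√k. The approach is exact in the limit
for star-shaped surfaces and loses validity for seeds with deep
concavities — a documented limitation, acceptable for the bean-like
material this tool targets. On synthetic spheres and ellipsoids the
reconstructed volume, area, section perimeters and areas sit within 0.5–1 %
of closed forms at default settings.

Volume is the sum of signed tetrahedra against the origin
(translation-invariant for closed meshes, asserted in tests), area the
triangle-area sum, and cross-sections are exact plane–mesh intersections:
crossing triangles yield segments whose endpoints are identified by the
*integer id of the mesh edge they lie on* — not by floating-point
coordinates — so loops chain robustly; the largest closed loop gives the
profile polygon, shoelace area and polyline perimeter.

## Phenotypes

Eleven size traits: V, S, L, W, T from cloud AABB, and C₁..C₃/A₁..A₃ from
the three principal sections (horizontal L×W with plane normal Y,
transverse L×T normal Z, longitudinal W×T normal X — the indexing
consistent with the bounding-rectangle denominators A₁/LW, A₂/LT, A₃/WT).
Twenty-two shape traits follow the standard formulas (see
`?shapePhenotypes`). Elongation is computed from the L/W/T ratios, not
from a best-fit ellipse: that is the operational definition consistent
with the rest of the trait table, and it reproduces the anchor identities
(0 for a circle, →1 for a long narrow profile). Cross-sections are taken
on the mesh rather than by re-slicing the cloud because only the mesh
yields closed polygons with well-defined perimeter and area.

## Statistical shape models

`buildShapeModel()` implements the correlation-PCA composite-weight
scheme: indicator signs (all +1 by default; no seed trait is treated as a
negative indicator), standardization by sample sd, eigendecomposition of
R = Z′Z/(n−1), retention of the smallest m components reaching the **80 %
cumulative-variance threshold**, loadings u = eigenvector·√λ, importance
aⱼ = Σₖ (λₖ/Σλ_retained)·|u_{jk}|, and weights wⱼ = aⱼ/Σa. Absolute
loadings are used because eigenvector signs are arbitrary; variance
proportions are computed within the retained components (an argument-free
design choice — computing them over all p only rescales the importance
vector). The two structural guarantees — all weights non-negative and
summing to exactly 1 — are validated by the class itself. A warning is
issued when n < p; the model is then descriptive rather than stable.

## The synthetic test bed

`makeSeedCloud()` samples r(u) = r_ellipsoid(u)·(1 + irregularity·P(u)) on
a Fibonacci direction lattice sized so the realized spacing matches the
request, where P is a smooth band-limited field (polynomial harmonics of
degree ≤ 4 with seed-specific coefficients, normalized to unit amplitude).
Defaults mirror bean-scale material: semi-axes 2–13 mm across species,
irregularity up to 0.1 for wrinkled types, coordinate noise σ = 0.005 mm,
and sampling spacing 0.1 mm for single seeds — a deliberate 10× coarsening
of a real scanner's 0.01 mm density, chosen once so that a full run stays
at desk scale (tens of seconds); scene generation coarsens further to
0.3 mm and draws roundish bean-like axis ratios (a 3.5–5.5 mm,
b/a 0.82–0.95, c/b 0.85–0.98), matching the material on which
batch segmentation is known to be clean. `occludeBottom()` removes a 30°
cap about −Y, the typical unscanned contact region; `makeScene()` rests
seeds on y = 0, thickness vertical, on a jittered grid with disjoint
bounding boxes, and records per-point labels plus the full truth clouds.

What passing tests on this bed *do* show: the geometry of every stage is
correct (exact recovery on exact inputs, closed-form agreement on spheres
and ellipsoids, label-perfect segmentation on separated seeds, completion
error at the scale of the injected noise). What they do *not* show:
robustness to reflective-surface dropouts, marker shadows, scan-stitching
artifacts, touching seeds, or non-star-shaped material — none of which
the generator emulates.

## Numerical choices and degenerate inputs

* Ellipse fitting centres and RMS-scales coordinates before building the
  6×6 scatter; raw mm coordinates at seed scale are too ill-conditioned.
* The eigenpair with positive constraint value is the unique ellipse
  solution; its absence (collinear or < 6 points) raises a degenerate-input
  error that `completeCloud()` converts into a warning, leaving that slab
  unfilled rather than failing the seed.
* Slabs are half-open intervals, last one closed, so every point belongs
  to exactly one slab; a cloud with zero x-extent degenerates to one slab.
* All randomized algorithms (RANSAC, generators) take explicit seeds and
  restore the caller's RNG state; identical seeds give bit-identical
  output, which the pipeline's byte-identical `traits.csv` test checks.
* k-NN searches use a hash-grid with a cell size from a sampled spacing
  estimate; degenerate (coincident-point) clouds fall back to unit cells.

## Problem sizes used in the checks

The shipped tests and the acceptance script run, per invocation: 20
single seeds at 0.1 mm spacing (~20–40k points each) through completion
and error evaluation; one 50-seed scene at 0.3 mm spacing (~300k points)
through full segmentation; and assorted smaller property checks. These
sizes were chosen as the smallest at which the quantities of interest are
measured well away from their tolerances, and they keep a complete run in
the tens of seconds to a few minutes on a single CPU.
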