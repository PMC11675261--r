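---
title: "Multi-source circular geodesic voting: model and implementation notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-source circular geodesic voting: model and implementation notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(geovote)
```

## The problem and the model

`geovote` delineates one closed object in a 2D image starting from weak,
automatically produced initialization: an interior center point `c` and a
handful of approximate boundary points, the format emitted by
polar-representation detectors (a center plus ray lengths at fixed angles).
Detector points are rarely on the true boundary, carry no regularity, and a
polar parameterization cannot represent boundaries that a ray crosses more
than once (U-shapes). The package converts this weak initialization into a
dense, geometrically regularized segmentation by geodesic voting: many
minimal paths are traced under edge-adapted metrics, and pixels crossed by
many paths are declared boundary.

The pipeline has four stages.

**1. Edge features and landmark rectification.** Channel gradients are taken
at scale `sigma` (Gaussian derivatives); their per-pixel outer product summed
over channels is the structure tensor `W`, whose trace
`f = lambda1 + lambda2` is the edge indicator. `f` is rescaled by its global
maximum to `fhat` in `[0, 1]` so the exponential weights below are
image-independent. A unit field `r` points towards the closest edge: the
edge set is `fhat > 0.2` after non-maximum suppression across the dominant
eigenvector, and `r` descends the Euclidean distance transform to that set
(on the edge itself, where that gradient vanishes, the dominant eigenvector
of `W` stands in). Each raw landmark is moved to the strongest edge point of
a geodesic neighbourhood: distances from the landmark are solved under the
Riemannian metric `M = t t' + exp(mu_R fhat) r r'` (cheap along edges,
exponentially expensive across), the neighbourhood keeps every pixel whose
realized minimal path has *Euclidean* length at most `xi`, and the rectified
point is the arg-max of `f` there, with ties broken by smaller geodesic
distance and then lexicographic order; a constant `f` keeps the raw point.

**2. Adaptive cuts.** Each rectified landmark gets a cut: the concatenation
of two curvature-penalized (Euler-Mumford elastica) minimal paths,
center-to-landmark and landmark-to-image-border, computed on the
orientation-lifted domain (pixels x direction bins) with energy
`integral phi(x, theta) (1 + tau^2 kappa^2) ds`. The orientation cost is
`phi(x, theta) = exp(-mu_phi g / max g)` with `g = <n, W n>` evaluated on
the perpendicular `n` of the travel direction, so traveling along an edge is
cheap. The concatenation is reparameterized so the landmark sits at the
exact middle index. The cut's barrier is its supercover rasterization
dilated by one pixel, and two offset source points are placed at
`+/- epsilon` along the cut normal at the landmark.

**3. Distance-competition voting.** Voting endpoints are sampled by farthest
point sampling seeded with the union of all rasterized cuts, spreading `K`
points over the whole image under the uniform metric. Per cut and per side
(left/right offset), geodesic distances are solved under the two mutually
reversed asymmetric quadratic metrics
`F(x, u) = sqrt(u' M u + max(0, <w, u>)^2)` with
`M = exp(-2 mu_R fhat) t t' + r r'` and `w = +/- eta fhat t`: each favours
one rotational sense along edges. The cut's barrier is an obstacle, so a
path from one side of the cut must travel the long way around the object to
reach endpoints behind it -- this is what forces circular paths to follow
the full boundary. For each endpoint the cheaper of the two metrics wins
(strictly cheaper selects the reversed metric; ties keep the first) and the
winning geodesic is backtracked. Votes accumulate per pixel over all
`2K` paths of all `J` sources. The pairwise flow-consistency branch (keep a
path pair only when its two terminal tangents are antiparallel below a
cosine threshold `zeta`) is implemented but off by default: the multi-cut
pipeline votes with the distance-competition paths only.

**4. Extraction.** The total vote map is binarized at
`threshold_fraction x (number of voting paths)` (with 1000 paths and the
default fraction 0.1 the absolute threshold is 100), closed with a radius-2
disc, the component enclosing the center is kept (nearest component with a
warning otherwise), holes are filled, and the region's inner boundary is
the single-pixel-wide closed contour. Accuracy against a ground-truth mask
is reported both as the precision fraction `|S n G| / |S|` and as the
conventional Dice `2|S n G| / (|S| + |G|)`; the two differ and both are
always printed, since the precision fraction rewards under-segmentation.

## Parameters

| name | default | unit | role |
|------|---------|------|------|
| `sigma` | 2 | px | gradient scale; 2 keeps the edge indicator stable under the noise levels the generator emulates |
| `mu_R` | 4 | -- | edge contrast of the rectification and voting metrics; crossing a strong edge costs `exp(4) ~ 55x` the tangential move |
| `mu_phi` | 1 | -- | edge contrast of the cut cost; deliberately mild, because a cut only needs to cross the boundary once -- strong discounts make cuts ride along the boundary, which blocks the very pixels the voting stage must reach |
| `eta` | 1 | -- | asymmetry of the voting metrics; 0 disables rotational preference |
| `tau` | 2 | px | curvature weight; turning radii below ~2 px are penalized |
| `n_angles` | 64 | bins | orientation resolution of the lifted grid (5.6 degrees) |
| `xi` | 6 | px | rectification reach; must exceed the detector's localization error |
| `epsilon` | 2 | px | offset distance, larger than the barrier dilation radius 1 |
| `K` | 100 | -- | voting endpoints per run |
| `threshold_fraction` | 0.1 | -- | binarization level as a fraction of the path count |
| `zeta` | -0.5 | -- | terminal-cosine threshold of the optional pairwise branch |
| `rho` | 3 | px | Chebyshev stencil radius of the planar solver |

The same contrast weight `mu_R` drives both the rectification metric and the
asymmetric voting metrics: both express edge adherence of paths, and the
image-independent `fhat` normalization makes one weight serve both. The cut
cost keeps its own weight `mu_phi` because its role is different (see
above).

## Numerical choices

*Planar eikonal solver.* Label-setting Dijkstra over moves to all primitive
integer vectors within Chebyshev radius `rho = 3` (32 moves). An edge weight
is the line integral of the metric along the move: midpoint quadrature over
unit-length pieces with bilinear interpolation of the tensor/vector fields.
A single midpoint evaluation would make long moves under-integrate varying
fields and bias comparisons between stencil radii. Priority-queue ties break
by lexicographic pixel order, so runs are deterministic. At radius 3 the
angular resolution bounds the error against a radius-5 reference at roughly
1.5% for eigenvalue ratios up to ~2; strongly anisotropic fields need a
larger `rho`, which is exposed in the control list. Asymmetric metrics are
evaluated one-sidedly on the travel direction, and distances are
direction-dependent as they must be.

*Obstacles.* Obstacle pixels are removed from the graph, and in addition any
move whose swept supercover touches an obstacle is rejected. Without the
sweep test a radius-3 move could hop a thin barrier diagonally or graze a
barrier corner, and the exact barrier-exclusion property of voting paths
would not hold.

*Lifted elastica solver.* States are (pixel, orientation bin). A motion
primitive moves along a primitive integer vector within radius 2; its
terminal orientation is the move's own angle snapped to the nearest bin, its
curvature is the wrapped orientation change divided by the move length, and
its energy is exactly `phi_mid * len * (1 + tau^2 kappa^2)`. Constant-
curvature arc primitives were considered and rejected: snapping arc
endpoints to grid nodes perturbs the realized length and breaks both the
exactness of the per-primitive energy and the tau -> 0 reduction to planar
weighted distances, which this scheme satisfies by construction. The
default 64 bins keep the angular discretization error of path energies
under the 3% tolerance used in the checks.

*Rectification windows.* Each landmark's eikonal problem is solved on a
window of half-width `ceil(xi) + 4` around it; the Euclidean-length cap
`xi` guarantees the neighbourhood cannot leave the window.

*Degenerate inputs.* A constant image has `f = 0` everywhere: rectification
returns the raw landmarks, the Riemannian tensor is the identity, the
elastica cost is uniformly 1, and geodesics are straight. A landmark on the
domain boundary gets a cut whose outward half is degenerate (the cut ends
at the landmark). Endpoints falling on a cut's barrier are skipped for that
source with a warning; endpoints walled off from an offset are dropped and
counted, never fabricated. Identical rectified landmarks produce duplicate
cuts and a warning.

*Open choices resolved.* The outward half of a cut starts with free
orientation at the landmark (a flag can force it to continue the inward
half's terminal orientation; unconstrained was kept as default because the
join pixel is shared anyway and the free choice never loses energy). The
left side's competition is decided from its own distance pair rather than
reusing the right side's selection, because it uses strictly more
information; a flag restores the shared variant. One endpoint set is shared
by all sources; endpoints on some other source's cut are skipped only for
that source.

## The synthetic generator

`make_scene()` emulates the deployment inputs end to end: a shape (disk,
ellipse, 5-lobed star, or U-shape) of diameter roughly 60% of a 128 x 128
image, foreground 0.7 on background 0.2, optionally a linear illumination
ramp (`+/- 0.1` across the image), Gaussian blur, brightness scaling, and
additive Gaussian noise, in that order. Landmarks are produced the way a
polar detector would: rays at equal angles from the center, the outermost
boundary crossing per ray (a polar representation keeps only the greatest
ray length, which is exactly why U-shapes defeat it), then a radial
perturbation uniform within 3 px -- half the default rectification reach.
Scene generation runs on a private seeded RNG stream, so regeneration is
bit-identical and the global RNG is untouched. `make_suite()` crosses
families with seeds and defaults to the adverse conditions (illumination
ramp, noise variance 0.01).

What passing on these fixtures does and does not show: the shapes are
star-convex or mildly non-convex with a single object and known contrast;
real CT slices add neighbouring structures of similar intensity, partial
volume effects, and anisotropic texture. The fixtures exercise every code
path (including the multi-crossing polar failure mode), not the full
difficulty of clinical data.

## Problem sizes used in the checks

The test suite runs the full pipeline on 128 x 128 scenes with 5 sources
and 100 endpoints (about 6 s per scene on one core), the source-count sweep
on 4 families x 3 seeds at 5 and 15 sources, and the solver oracles on
24 x 24 grids where the dense radius-5 reference is affordable in plain R.
These sizes match the working scale of the CT crops the method targets
(roughly 100-150 px across).

## Limitations

- Single closed object per run; no multi-object handling.
- 2D only; pixel spacing is assumed isotropic.
- The polar-detector emulation perturbs true boundary points radially; it
  does not model detector outliers or missing rays, and rectification has
  no outlier rejection by design.
- The planar stencil solver trades accuracy for robustness on strongly
  anisotropic metrics; the voting metrics are extremely anisotropic along
  edges, where path *selection* (not distance accuracy) is what matters.
- The optional pairwise flow-consistency branch is implemented and tested
  but not part of the default pipeline.
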