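# geovote

Multi-source circular geodesic voting for image segmentation.

`geovote` delineates a single closed object in a 2D grayscale or color
image starting from the weak initialization that polar-representation
detectors (PolarMask-style networks) produce: one center point inside the
object plus a set of approximate, clockwise-ordered boundary points. Such
detector output is sparse, irregular, and cannot represent boundaries a
polar ray crosses more than once. The package turns it into a dense,
geometrically regularized segmentation, aimed at tasks like liver contour
delineation in CT crops of roughly 100–150 px.

## The method

Given an image `I`, a center `c` and landmarks `p̃_1 … p̃_J`:

1. **Edge features.** Gaussian-derivative gradients at scale `σ` build the
   structure tensor `W = ∇I ∇Iᵀ` (summed over channels); the edge indicator
   is its trace `f = λ₁ + λ₂`, and a unit field `r` points towards the
   nearest edge.
2. **Rectification.** Each landmark moves to
   `p_j = argmax f` over the geodesic neighbourhood
   `T_ξ(p̃_j) = {x : L(γ*_{p̃_j,x}) ≤ ξ}`, where paths are minimal under the
   Riemannian metric `R = t tᵀ + exp(μ_R f̂) r rᵀ` and `L` is the Euclidean
   length of the realized path.
3. **Adaptive cuts.** Per landmark, a cut `C_j = C_{1,j} ⋓ C_{2,j}`
   concatenates two Euler–Mumford elastica minimal paths
   (`∫ φ(x, θ)(1 + τ²κ²) ds`, solved on the orientation-lifted grid
   `Ω × S¹`) from the center through `p_j` to the image border. The cut is
   a barrier that circular geodesics may neither cross nor touch.
4. **Distance-competition voting.** `K` endpoints are spread by farthest
   point sampling. From two offset sources `p_j ± εN_j`, geodesic distances
   are solved under the mutually reversed asymmetric quadratic metrics
   `F(x,u) = sqrt(uᵀMu + ⟨ω,u⟩₊²)`, `ω = ±η f̂ t`; per endpoint the cheaper
   sense wins and its geodesic is backtracked. Votes
   `V = Σ_j V_j` count path coverage per pixel.
5. **Extraction.** `V` is thresholded at `threshold_fraction ×` (number of
   paths) — 100 when 1000 paths meet the default fraction 0.1 — refined by
   morphology, and reduced to a filled region plus a single-pixel closed
   contour. Accuracy is reported both as the precision fraction
   `|S∩G|/|S|` and as the conventional Dice `2|S∩G|/(|S|+|G|)`.

## Worked example

No data download is needed: the package generates its own detector-style
scenes with known ground truth.

```r
library(geovote)

scene <- make_scene(scene_descriptor("disk", seed = 0, noise_var = 0.01,
                                     n_landmarks = 5))
fit <- geovote(scene$image, scene$landmarks, truth = scene$truth_region)
print(fit)
#> Multi-source circular geodesic voting segmentation
#>   sources (landmarks): 5   endpoints: 100   voting paths: 1000
#>   region: 5007 px   contour: 225 px   threshold: 100
#>   score (|S&G|/|S|): 0.9249   Dice: 0.9610

plot(fit)        # image + contour + rectified landmarks
```

The five perturbed landmarks were pulled back onto the true boundary, the
1000 voting paths (2 sides × 100 endpoints × 5 sources) concentrated on
the circle, and the extracted region overlaps the ground-truth disk with a
Dice of 0.961; the precision fraction 0.925 says 92.5% of the predicted
pixels lie inside the true region. `summary(fit)` adds per-stage timings,
`write_geovote(fit, dir)` dumps the rectified landmarks, cuts, voting map,
contour and region to disk, and `inst/scripts/geovote` wraps the same
pipeline as a shell command (`geovote run / synth / sweep`).

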