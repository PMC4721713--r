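---
title: "Pupil and glint detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pupil and glint detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilglint)
```

## The problem

Pupil center–corneal reflection (PCCR) gaze trackers need two things from
every near-infrared eye image: the subpixel center of the pupil and the
subpixel centers of the corneal reflections ("glints") of the NIR LEDs.
Under NIR illumination the pupil is the darkest structure in the frame, the
iris a mid-gray annulus, skin and sclera bright, and glints small
near-saturated blobs. `pupilglint` implements a complete detection pipeline
for such images: three-class optimal thresholding, morphological cleanup,
projection-based rough localization, ray-casting boundary detection with
interference elimination (circular ring rays location, CRRL), constrained
total-least-squares (TLS) ellipse fitting, and log-linearized 2-D Gaussian
glint fitting.

All coordinates are 0-based with `x` = column and `y` = row and pixel
centers at integer positions; the upstream description of the method never
states a convention, and this one matches the raster order of common image
formats.

## Three-class threshold selection

Gray levels are split into `G0 = {0..T1}` (pupil, lashes), `G1 =
{T1+1..T2}` (iris, shadow), `G2 = {T2+1..255}` (skin, sclera). For a
candidate pair the class probabilities `omega_k`, means `h_k` and variances
`sigma_k^2` give the within-class variance `sigma_W^2 = sum omega_k
sigma_k^2` and the between-class criterion

```
g(T1, T2) = omega_0 (h_0 - h)^2 + omega_1 (h_1 - h)^2 + omega_2 (h_2 - h)^2 ,
```

which `solve_thresholds()` maximizes exhaustively over the grid `T1 in
[1, 50]`, `T2 in (T1, 150]`. Those ranges encode where the pupil/iris and
iris/skin boundaries fall in NIR eye images and cut the search to ~7.5k
pairs; prefix sums of `p_i`, `i p_i`, `i^2 p_i` make each evaluation O(1).
The histogram is taken after 3x3 mean smoothing, which thins the histogram
valleys between modes.

Design choices worth knowing:

* The continuous-approximation stationarity conditions (`2 T1 = h0 + h1`,
  `2 T2 = h1 + h2`) are reported as diagnostics but never used for solving.
  Their derivation is not rigorous for a discrete histogram and no
  combination rule with the grid criterion is specified anywhere; the
  exhaustive argmax is exact, fast, and has no convergence questions.
* Ties are broken toward the smallest `T1`, then the smallest `T2`, so
  plateau cases (well-separated spikes) are deterministic.
* An empty class gets its range midpoint as mean and variance 0, flagged.
  An `omega_k = 0` class contributes nothing to either `sigma_W^2` or `g`,
  so the law-of-total-variance identity `sigma_W^2 + g = Var(histogram)`
  holds regardless — the property the test suite uses as a cross-check.

## Morphology and rough localization

Binarizing at `T1` (pupil = below) leaves lash fragments and glint holes.
Opening with a `0.3 T1` square element removes thin dark strokes; closing
with `0.7 T1` fills holes. Sizes are rounded then raised to the nearest odd
integer `>= 3` so the element has a center pixel (`T1 = 13` gives 5 and 9).
Borders count as background. Note one upstream figure caption mentions a
single 5x5 element while the text prescribes the two `T1`-scaled sizes; the
configuration follows the text (`morph.open_factor`, `morph.close_factor`),
and a single size can be forced by setting both factors equal.

Column and row foreground counts of the cleaned mask give the pupil box.
The box is the **longest contiguous positive run** in each profile — not
first/last nonzero — so a surviving speck elsewhere cannot stretch it. The
rough center is `op' = (l1 + l2/2, l3 + l4/2)` and the rough radius
`rp' = (l2 + l4)/4`, exactly as printed in the source method (this box
convention carries a half-pixel bias that the later stages absorb).

## CRRL boundary collection

36 rays at 10 degree spacing are cast from radius `0.5 rp'` to `1.5 rp'`
around `op'`, sampled every 0.5 px with bilinear interpolation of the
gradient amplitude. Samples at or above `Delta = 1.4 * delta` with
`delta = T2 - T1` are marked; runs of marked samples separated by at most
one unmarked sample form clusters; a cluster's representative is its
maximum-amplitude sample. Rays with exactly one cluster survive; all other
rays are discarded wholesale (a glint rim or reflection inside the annulus
produces extra clusters). Survivors are refined by fitting a cubic spline
to the amplitude over the representative +/- 2 samples and taking its
argmax; monotone windows clamp and are flagged unrefined.

Numerical and interpretation choices:

* **Gradient scaling.** Gradients use the conventional *unnormalized* 3x3
  Sobel kernels: a sharp step of height `h` yields amplitude `4h`, a smooth
  ramp of slope `s` yields `8s`. A description elsewhere of a 1/8-normalized
  Sobel is internally inconsistent (1/8 gives `h/2` for a unit step, not
  `h`) and — decisively — incompatible with the threshold: with
  `delta ~ 100` the threshold `1.4 delta = 140` would exceed the largest
  amplitude any 8-bit edge can produce under 1/8 scaling (a full 0-255 step
  gives 127.5). Only the unnormalized convention makes typical pupil/iris
  contrasts (edge amplitudes of 200-400) clear the stated threshold, so
  that is what the implementation uses.
* **Threshold semantics.** "Within the range" of `Delta in [1.3 delta,
  1.5 delta]` is read as *at or above* one chosen coefficient (default
  1.4): a literal band-pass would reject every strong true edge (its peak
  overshoots the band and its two shoulders would each produce a cluster).
  The literal band is available as `crrl.band: true` for inspection.
* **Cluster counting.** Counting raw supra-threshold samples would count
  every edge 4-6 times at 0.5 px sampling and eliminate every ray; merging
  adjacent samples into clusters is the only operable reading of the
  per-ray count rule.
* Gradients are computed on the unsmoothed image (sharper edges); the
  smoothed image feeds only the histogram. `crrl.use_smoothed` flips this.

## Constrained TLS ellipse fit

The conic `A x^2 + B xy + C y^2 + D x + E y + F = 0` under `A + C = 1`
becomes the linear model `B(xy) + C(y^2 - x^2) + D x + E y + F = -x^2`.
Centering the four regressors and the response eliminates the intercept
(recovered afterwards from the means), giving an n x 4 errors-in-variables
system solved by the deflated normal equations

```
tau' = (X'X - gamma_min^2 I)^{-1} X'Z ,
```

with `gamma_min` the smallest singular value of `L = [-Z, X]`, computed by
a self-contained cyclic Jacobi eigendecomposition of `L'L` (rotations
annihilate off-diagonal entries until the off-diagonal Frobenius norm falls
below `1e-12 ||Q||_F`; 50-sweep cap). The pupil center is the conic's
closed form `xp = (BE - 2CD)/(4AC - B^2)`, `yp = (BD - 2AE)/(4AC - B^2)`.

**Coordinate normalization.** `fit_ellipse()` internally maps the points to
their centroid and scales to unit RMS radius, then transforms the conic
back exactly (the quadratic coefficients — and hence `A + C = 1` — are
unaffected; linear and constant terms rescale). This matters twice over:

1. *Conditioning.* At raster scale the regressors `xy` and `y^2 - x^2` are
   ~100x larger than `x` and `y`; squaring into normal equations then costs
   ~10 digits and noiseless fits would miss the 1e-9 center tolerance.
2. *Correct TLS weighting.* The uniform deflation `gamma^2 I` models equal
   error variance in every column. In raw coordinates the per-column error
   scales differ by orders of magnitude and the deflation over-corrects the
   small columns — measured as a ~20x *increase* of center error over
   plain LS under 1 px coordinate noise. Normalization approximately
   equalizes the column error variances, the regime the TLS model assumes.

**TLS vs LS, honestly.** With boundary points spread over the whole
contour, the leading LS bias from noisy quadratic regressors perturbs the
fitted *axes*, not the center (it cancels by symmetry), so TLS and LS
center errors coincide to ~1e-4 px and which median is smaller is
essentially a coin flip across seeds. The acceptance test for the "TLS at
least as good as LS" property therefore certifies only that the deflation
does no harm in the normalized frame; it should not be read as evidence of
a practical accuracy gain. Where TLS demonstrably helps is the guarantee
side: near-consistent systems (`gamma_min ~ 0`, sensitivity ratio near 1)
recover the generating conic exactly.

Degenerate inputs: fewer than 6 points or a rank-deficient design raise
errors; an ill-conditioned deflated matrix (condition > 1e12) triggers a
small flagged ridge, then a flagged fall-back to ordinary LS.

## Glint detection

Pixels at or above 240 are thresholded, filtered by a 2x2 open-close, and
labeled (8-connectivity); components with area in `[4, 400]` px become
regions, numbered in row-major order. Within each region box (dilated by
1 px) the pixels with intensity at least `0.2 x` the region maximum — and
strictly below 255 — enter the log-linear fit `ln I = a x^2 + b y^2 + c x +
d y + e`, solved by the same deflated-TLS machinery in region-local
coordinates; the center is `(-c/2a, -d/2b)`, the spreads
`sqrt(-1/2a), sqrt(-1/2b)`, and the amplitude the model value at the
center. Fits with `a >= 0` or `b >= 0`, fewer than 6 usable pixels, or a
center escaping the dilated box are rejected.

Choices: exactly saturated pixels are excluded because their clipped values
bias the paraboloid; the `0.2 x max` floor plays the role of the halo
boundary (an explicit spline contour adds nothing to a dense paraboloid
fit, recorded as a deviation); region-local coordinates keep `e` — which
grows quadratically with distance from the origin — well scaled. Because
the support is symmetric about the peak, the additive iris/skin background
and the clipped plateau bias the *spread and amplitude* estimates but not
the center, which is the quantity downstream gaze estimation consumes.

## Synthetic scenes: what they do and do not establish

`sample_scene()` draws pupils with semi-axes 25-70 px (tilt up to ~30
degrees), grays pupil 10-30 / iris 100-140 / background 180-230, four
glints with amplitude 245-255 and spreads 1.8-3.0 px in a 2x2 grid (wider
than tall, as an LED array reflects), Gaussian blur sigma 1 px, and sensor
noise sigma 2 gray levels; the pupil edge is anti-aliased over a 2 px
coverage band so subpixel refinement has a realistic gradient profile
rather than a trivially exact hard edge. The spread range is chosen so a
glint's >= 240 component survives the 2x2 opening and the minimum-area
filter; clean scenes place glints on the iris (a ~2 px spread glint on a
~20-gray pupil thresholds to a component below the area floor — supported
by the renderer, not the default). With these choices `delta = T2 - T1`
lands near 100 and edge amplitudes clear `1.4 delta` by a comfortable
margin.

What a green test on these scenes does **not** establish: performance on
real eyelid/eyelash occlusion geometry, skin reflections, off-axis
distortion, inter-subject iris texture, or motion blur. The renderer has no
iris texture at all, so the iris interior is flat — real images produce
weak gradient clutter inside the annulus that the threshold must reject.
Published stability/error figures for the original method were measured on
subject datasets that are not distributable, so no number produced here is
comparable to them; the evaluation module reproduces the *semantics*
(stability = percentage of successes, success declared at center error
<= 5 px since no operational definition is printed; RMS over successes
only) on synthetic batches.

## A known red acceptance property

The test suite asserts, per its acceptance contract, that no surviving
boundary point lies within any glint's 2-sigma footprint on
contour-glint scenes. This is **not attainable** under the printed
elimination rule, and the test is intentionally left failing (~3% of
surviving points across 100 scenes):

* a ray passing the contour glint at 1.2-2 sigma lateral offset sees a
  glint tail too weak to raise a second cluster above `1.4 delta`, yet
  strong enough to bias the edge's gradient peak up to a few px inward —
  sub-threshold interference is invisible to any per-ray counting rule;
* a glint sitting just outside the contour can have its supra-threshold
  gradient region *overlap* the pupil edge's, merging into a single
  cluster whose maximum-amplitude representative lands on the glint rim.

The companion property — center RMS on contour-glint scenes within 1 px of
clean scenes — passes with a wide margin (~0.24 vs ~0.07 px), which is the
operationally relevant guarantee: a handful of biased points among ~33
survivors barely moves the TLS fit.

## Worked example

```{r example, eval = FALSE}
tr <- sample_scene(7, "clean")          # reproducible ground truth
img <- render_eye(tr)
res <- detect(img)
res
#> <detection_result: pupil (238.21, 285.44), 4 glint(s)>
tr$pupil$center                          # truth: (238.19, 285.44)
report <- score(list(res), list(tr))
report
```

## Configuration reference

| key | default | meaning |
|---|---|---|
| `otsu.t1_range` | `[1, 50]` | search range for `T1` (gray levels) |
| `otsu.t2_max` | `150` | upper bound for `T2` |
| `otsu.smooth` | `true` | histogram from the 3x3-smoothed image |
| `morph.open_factor` | `0.3` | opening element = `0.3 T1` (odd, >= 3) |
| `morph.close_factor` | `0.7` | closing element = `0.7 T1` |
| `crrl.n_rays` | `36` | rays across the annulus |
| `crrl.inner`, `crrl.outer` | `0.5`, `1.5` | annulus radii x `rp'` |
| `crrl.delta_coeff` | `1.4` | threshold = coeff x `(T2 - T1)` |
| `crrl.step` | `0.5` | ray sampling step (px) |
| `crrl.band` | `false` | literal band-pass threshold reading |
| `crrl.use_smoothed` | `false` | gradients from the smoothed image |
| `fit.min_points` | `6` | minimum surviving boundary points |
| `fit.cond_limit` | `1e12` | deflation conditioning guard |
| `glint.threshold` | `240` | glint binarization level |
| `glint.min_area`, `glint.max_area` | `4`, `400` | component area bounds (px) |
| `glint.support_frac` | `0.2` | fit-support floor x region max |
| `eval.success_radius` | `5` | pupil success radius (px) |
| `eval.glint_match_radius` | `3` | truth-to-detection match radius (px) |
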