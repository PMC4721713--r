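# pupilglint

Subpixel pupil-center and glint-center detection in near-infrared eye
images, for pupil center–corneal reflection (PCCR) gaze tracking.

Under NIR illumination an eye image has a characteristic trimodal structure:
a dark elliptical pupil (the lowest grays), a mid-gray iris annulus, and
bright skin/sclera, plus a grid of small near-saturated LED reflections
(glints) on the cornea. `pupilglint` turns one such 8-bit grayscale frame
into a subpixel pupil center, a fitted pupil ellipse, and one fitted
2-D Gaussian per glint.

## Method

The pipeline, stage by stage:

1. **Three-class thresholding.** After 3x3 mean smoothing, two thresholds
   `(T1, T2)` split the histogram into pupil / iris / skin classes by
   exhaustively maximizing the between-class variance criterion
   `g(T1,T2) = Σ_k ω_k (h_k − h)²` over `T1 ∈ [1,50]`, `T2 ∈ (T1,150]`
   (prefix sums make each evaluation O(1)).
2. **Morphological cleanup.** Binarize at `T1` (pupil = below), open with a
   `0.3·T1` square element (removes lash strokes), close with `0.7·T1`
   (fills glint holes).
3. **Rough localization.** Column/row foreground projections; the longest
   positive runs give the pupil box, rough center
   `op′ = (l1 + l2/2, l3 + l4/2)` and rough radius `rp′ = (l2 + l4)/4`.
4. **CRRL boundary detection.** 36 rays at 10° spacing cross the annulus
   `[0.5 rp′, 1.5 rp′]`; samples whose Sobel gradient amplitude reaches
   `Δ = 1.4 (T2 − T1)` form clusters; rays with anything other than exactly
   one cluster are discarded (glint/reflection interference); survivors are
   refined to subpixel by a cubic-spline argmax along the ray.
5. **Constrained TLS ellipse fit.** The conic `Ax² + Bxy + Cy² + Dx + Ey +
   F = 0` with `A + C = 1` is fitted by total least squares: centered
   regressors, deflated normal equations
   `τ′ = (XᵀX − γ²_min I)⁻¹ XᵀZ` with `γ_min` the smallest singular value
   of `[−Z, X]` from a self-contained Jacobi eigensolver. Pupil center:
   `x_p = (BE − 2CD)/(4AC − B²)`, `y_p = (BD − 2AE)/(4AC − B²)`.
6. **Glint fitting.** Threshold at 240, 2x2 open-close, connected
   components (area 4–400 px); per region, `ln I = ax² + by² + cx + dy + e`
   is solved by the same TLS machinery and the center is `(−c/2a, −d/2b)`.

A seeded synthetic-eye renderer with exact ground truth
(`sample_scene()` / `render_eye()`) and a stability/RMS scorer (`score()`)
close the loop for testing and evaluation.

Coordinates are 0-based, `x` = column, `y` = row, pixel centers at
integers. See `vignettes/pupilglint-methods.Rmd` for the full model,
parameter and design documentation.

## Worked example

```r
library(pupilglint)

tr  <- sample_scene(7, "clean")   # randomized scene with exact ground truth
img <- render_eye(tr)             # 640x480 8-bit NIR-like eye image
res <- detect(img)
res
#> <detection_result: pupil (238.21, 285.44), 4 glint(s)>

tr$pupil$center                   # truth
#> [1] 238.1871 285.4385          # detected center is ~0.03 px away

res$diagnostics$thresholds
#> <threshold_pair T1 = 50, T2 = 150 (delta = 100), g = 1133.860>

res$glints[[1]]
#> <glint_fit #1: center (309.15, 259.75), sigma (4.50, 5.93), H = 261.2>
#  truth for that glint: (309.10, 259.81) -> ~0.08 px error

score(list(res), list(tr))
#> <eval_report over 1 image(s):
#>   pupil: stability 100.0%, RMS error 0.032 px
#>   glint: stability 100.0%, RMS error 0.096 px>
```

The printed pupil center is the closed-form center of the fitted conic;
`diagnostics` carries the thresholds, rough box, surviving rays and
boundary points of every stage. On batches of 100 clean synthetic scenes
the pipeline measures ~100% pupil stability with ~0.1 px RMS center error
and ~0.05 px glint RMS error (see `tests/testthat/test-acceptance.R`);
note these are synthetic-scene numbers, not comparable to figures measured
on real subject datasets.

## Command line

```sh
Rscript inst/cli/pupilglint detect --image eye.png --json out.json --overlay out.png
Rscript inst/cli/pupilglint batch  --glob 'frames/*.png' --out results.csv
Rscript inst/cli/pupilglint synth  --n 100 --difficulty contour_glint --seed 42 --out dir/
Rscript inst/cli/pupilglint eval   --images dir/ --truth dir/ --report report.json
```

`detect` reads PNG/JPEG/PGM/PPM (color inputs are luma-converted). JSON
output nests `pupil {x, y, conic}`, `glints [{id, x, y, sigma_x, sigma_y,
amplitude}]` and `diagnostics {T1, T2, delta, n_rays_surviving}`; CSV is
one flat row per image (`pupil_x, pupil_y, glint1_x, glint1_y, ...`) with
2-decimal floats and `NA` markers. Any stage parameter can be overridden
with `--config cfg.yaml` (keys in the vignette's configuration table).

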