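---
title: "Adaptive phase contrast microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive phase contrast microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcmicro)
```

## The problem

Phase contrast requires the image of the condenser annulus to overlap the
phase ring in the objective's back focal plane. In a microtiter-plate well
the liquid surface is curved (the meniscus effect): away from the well
center the inclined air–liquid interface refracts the illumination, so the
annulus image is displaced radially outward and phase contrast collapses
into brightfield. A transmissive LCD in place of the fixed condenser
annulus can re-center the annulus for every imaging position, provided
three computational pieces work reliably:

1. **Ring detection** — measure the annulus/phase-ring center offset
   `Δd` (px) in a Bertrand-lens pupil image;
2. **Linear calibration** — map that offset to the corrective LCD position
   via `p = k·Δd + p0`;
3. **Area quantification** — score how much of a full-well image actually
   shows phase contrast, using background brightness as the indicator.

`apcmicro` implements these three pieces plus the surrounding acquisition
planning (tile layout, four-anchor autofocus, known-coordinate mosaic
assembly) and a seeded synthetic-optics simulator that emulates the
meniscus so that every stage can be exercised and benchmarked without
microscope hardware.

## The synthetic optics model

No public dataset of Bertrand-lens well images exists, so the package
carries a phenomenological simulator ([`meniscus_model()`]) whose defaults
define the study conditions used throughout the tests:

* **Radial shift law** `s(r) = shift_gain · r · r̂` with
  `shift_gain = 15` px/mm: the displacement is linear in the radial
  distance from the well center and directed outward. No functional form
  for the meniscus profile is established for this geometry; linearity is
  the simplest monotone law consistent with a linear compensation mapping,
  and the package treats it as a stand-in, not physics.
* **Distortion**: the annulus axis ratio decays as `1 − 0.02·r` (minor
  axis along the radial direction), emulating the elliptical distortion of
  the annulus near the well edge. This is why detection fits an ellipse,
  not a circle.
* **Gray levels**: phase-contrast background 70, brightfield 220 on the
  8-bit scale; additive Gaussian noise with σ = 3 (5 in the detection
  benchmark). Ring bands are rendered with error-function edges of 2 px
  softness — hard edges would make thresholding trivially easy.
* **Bertrand geometry**: 960×800 px frames, phase-ring band radii
  120–160 px, annulus band radii 130–150 px, i.e. the annulus nests inside
  the phase ring at perfect alignment.
* **Reflections**: optional bright discs (radius 5–15 px) outside the
  annulus emulate the false-positive sources the contour filters must
  reject.
* **Well mosaics**: a 2000 px square image of a circular well
  (radius 47.5% of the side). The phase-contrast region is a centered disc
  sized to the requested area fraction; brightness ramps to brightfield
  over a logistic transition whose 10–90% width is 5% of the well radius,
  placed just *outside* the phase disc (the disc boundary is where
  brightness starts to rise). Optional cell-like speckle (blurred noise,
  stronger inside the phase region where cells are visible at high
  contrast) emulates specimen texture.

What the simulator does **not** emulate: physically based refraction,
shading and vignetting of real objectives, camera fixed-pattern noise,
debris, partial wells, or stitching seams from feature-based registration.
Tests passing on this model demonstrate the algorithms' correctness and
robustness margins under controlled conditions; they do not certify
performance on any particular microscope.

All generators are seeded and byte-deterministic: identical seeds and
parameters produce identical images.

## Ring detection

The detection pipeline mirrors classical CV practice: downscale to 20%
(`downscale = 0.2`; all offsets and the acceptance margin are expressed at
this analysis scale), CLAHE (clip 2.0, 8×8 tiles), binary threshold,
connected components with hole filling, Suzuki-style outer-border
extraction, then filters on contour area and roundness

\[ o = \frac{4\pi A}{P^2}, \]

which is 1 for a circle and π/4 ≈ 0.785 for a square. Candidates with
`o < 0.7` (default) are rejected; among survivors the largest area wins,
the true ring being the dominant pupil structure.

Two numerical choices deserve note:

* **Roundness on the convex outline.** Chain-code step lengths
  overestimate the perimeter of digitized circles by ~5%, which would bias
  the roundness of a genuine circle to ≈ 0.90. The package therefore
  computes `A` and `P` on the exact polygon through the convex hull of the
  boundary pixels: discrete circles then score ≈ 1 and squares exactly
  π/4. Ring outer contours are convex, so nothing is lost for the shapes
  being filtered.
* **Segmentation thresholds.** CLAHE with clip limit 2 compresses the
  background toward mid-gray (roughly 140–170 on our synthetic pupils)
  while pushing the annulus above 200 and the phase ring below 80. The
  default thresholds are therefore 190 for the bright annulus and 130
  after inversion for the dark phase ring, placed centrally in the
  post-CLAHE gaps between the band and background populations. Like every
  detector parameter they are configuration, not constants; real pupils
  will need their own values, which is why two independent parameter
  blocks (`annulus_params()`, `phase_ring_params()`) exist.

The ellipse is fitted to the convex hull of the selected contour — the
hull restores support where the annulus is dimmed by the phase ring — with
Taubin's approximate mean-square algebraic criterion, solved as a 5×5
generalized eigenproblem after isotropic normalization. The fit is exact
on noise-free conic data and needs at least five points; collinear or
non-elliptical solutions raise a fit error.

The phase-ring center is detected once per session from a white-screen
calibration image and passed to `detect_offset()` for all subsequent
tiles; only the annulus is re-found per tile.

### Benchmark

`run_benchmark()` replays the validation protocol on synthetic data: 500
Bertrand images with per-axis offsets uniform in [0, 60] px (full
resolution, random sign), up to 3 reflection distractors, noise σ = 5.
Euclidean annulus-center errors are summarized against the 15.0 px
acceptance margin (at the analysis scale) below which phase contrast is
still preserved. On the synthetic model the median error is well below a
pixel — cleaner than manual labeling of real pupils, as expected from a
simulator without label noise.

## Linear calibration

Because the optics between LCD and phase-ring plane are linear, offsets
map to LCD positions through `p = k·Δd + p0` with one scalar `k`
(mm/px) shared by both axes. `fit_calibration()` pools the magnitudes
|Δp| over both axes and regresses them on |Δd|; `p0` comes from a
zero-offset pair when one was recorded, otherwise from per-axis regression
intercepts. The pooled fit uses a free intercept by default: folding noisy
magnitudes biases small-|Δd| points upward, and the intercept absorbs that
bias instead of tilting the slope (an origin-forced fit is available via
`intercept = FALSE`). Noiseless pairs are recovered to floating precision;
with 2 px offset noise and 0.1 mm position noise over 20 pairs the slope
is recovered within a few percent of the reference value 0.0113 mm/px.

`render_annulus_frame()` rasterizes the corrective annulus as a strict
black-and-white LCD matrix (no anti-aliasing), with a white-screen mode
for the brightfield calibration step.

## Area quantification

`quantify_area()` scores a full-well image by background brightness:

1. downscale so the longest side is ≤ 2000 px (full-well composites are
   huge);
2. Gaussian blur (σ = 8 analysis px) so the local background dominates
   over cell texture;
3. thresholds from the blurred image: `g_ph` is the mean of the 5×5
   neighborhood at the well center (a single pixel would be noise-bound),
   `g_br` the mean of the top 10% of the horizontal cross-section through
   the center (the quantile is configurable; the cross-section reaches the
   brightfield corners, so its top decile is a robust brightfield
   estimate). The window is the 15% interval on either side:
   `t_upper/lower = g_ph ± 0.15·(g_br − g_ph)`. A gap `g_br − g_ph` below
   10 gray levels raises a degenerate-contrast error — with no
   phase/brightfield distinction the area is undefined;
4. binarize to `[t_lower, t_upper]`, erode with a disc of radius 2% of the
   well radius to sever bridges to peripheral look-alike regions, keep the
   connected component containing the center (or, if erosion removed the
   center pixel, the component nearest it), dilate with the same element
   to restore the patch, and clip to the well circle;
5. report patch pixels divided by `π·R²`, the well modeled as a circle of
   known radius.

The symmetric erosion/dilation pair cancels at the patch boundary to first
order, so the area estimate is unbiased for smooth boundaries; blur does
bleed brightfield into the outermost ~σ pixels of the rim, which is why a
fully phase-gray well scores ≈ 0.94 rather than 1.0. On textured synthetic
mosaics the estimate lands within ±2 percentage points of truth across the
5–42% range of interest, and within ±2 points with texture off over
fractions 5–40%.

`summarize_wells()` reproduces the per-well comparison table: means,
spreads and adaptive/conventional ratios. Ratios are kept at full
precision and only rounded for display; the spread is the population
standard deviation, since the wells reported are the population measured.

## Focus metrics

`tenengrad()` is the mean over interior pixels of the squared 3×3 Sobel
gradient magnitude. Per-pixel normalization (rather than a total) makes
scores comparable across image sizes; the score is zero on constant images
and scales with the square of contrast. `mean_gray()` is the plain image
mean. Over a displacement sweep the two move in opposition — sharpness
peaks and brightness bottoms at zero displacement — and their Pearson
correlation on the synthetic sweep is strongly negative (≤ −0.9),
supporting background brightness as the single phase-contrast indicator:
unlike sharpness it does not depend on specimen density or focus quality.

## Acquisition planning

`plan_tiles()` lays a rectangular grid with pitch `fov − overlap`
(default overlap 10% of the fov) over the well's bounding box and prunes
tiles that miss the disc; construction guarantees full coverage.
`focus_map()` takes the four autofocus anchors (default layout:
half-radius on the ±x/±y axes, a choice not dictated by any reference) and
interpolates/extrapolates focal z from their least-squares plane — exact
when the anchors are coplanar, which is also the only case in which the
"interpolation reproduces each anchor" contract can hold for four points.
`assemble_mosaic()` places tiles at their known grid coordinates with
linear feathering across overlaps, optional flat-field division (blurred,
edge-replicated reference) and an additive histogram offset matching each
tile's mean to the mosaic over their overlap. Feature-based stitching is
deliberately replaced by known-coordinate placement: tile positions are
exact in simulation, and registration is out of scope.

## Problem sizes and determinism

The test-suite and acceptance experiments use 960×800 Bertrand frames
(192×160 at analysis scale), 500-image benchmarks, 2000 px mosaics for the
headline fractions and 560–1000 px mosaics for property suites — sizes
chosen to exercise the algorithms at realistic scale while keeping a full
run in the minutes range on one CPU. Every stochastic step flows from an
explicit integer seed through R's RNG, restored afterwards, so results are
reproducible to the byte.

## Known limitations

* The meniscus laws (linear shift, linear axis-ratio decay, logistic
  brightness ramp) are stand-ins; real wells will deviate, and the
  detector/quantifier parameters are exposed as configuration for exactly
  that reason.
* Default segmentation thresholds are tuned to the synthetic pupil's
  post-CLAHE histogram and will need re-tuning on real cameras.
* The area algorithm assumes the well is imaged centrally and phase
  contrast holds at the image center; an off-center well or a center
  without phase contrast violates its premises (degenerate-contrast error
  at best).
* No sub-pixel refinement beyond the ellipse fit; no deep-learning
  detector; no color.
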