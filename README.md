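# apcmicro

Computational core of **adaptive phase contrast microscopy** for
microtiter plates.

Phase contrast needs the image of the condenser annulus to overlap the
phase ring in the objective's back focal plane. In a microtiter-plate well
the curved liquid surface (the meniscus effect) refracts the illumination:
away from the well center the annulus image is displaced radially outward,
and phase contrast degrades into brightfield. Replacing the fixed annulus
with a ring rendered on a transmissive LCD makes the annulus position
adjustable per imaging position — if software can (a) measure the
misalignment, (b) turn it into a corrective LCD position, and (c) verify
how much of the well actually shows phase contrast. `apcmicro` implements
those three pieces for people building or evaluating such systems:

* **Ring detection** (`detect_offset()`, `run_benchmark()`): classical CV
  pipeline on Bertrand-lens pupil images — 20% downscale, CLAHE, binary
  threshold, Suzuki-style outer contours filtered by area and roundness
  *o* = 4πA/P², convex hull, Taubin approximate mean-square ellipse fit —
  yielding the annulus/phase-ring center offset Δd in pixels.
* **Linear calibration** (`fit_calibration()`, `map_offset_to_lcd()`,
  `render_annulus_frame()`): the corrective LCD position follows
  **p = k·Δd + p₀** with a single scaling factor *k* (mm/px) shared by
  both axes, fitted by pooled-magnitude least squares from
  offset/position pairs.
* **Phase-area quantification** (`quantify_area()`,
  `summarize_wells()`): background-brightness algorithm for full-well
  images — blur, relative thresholds
  **t<sub>upper/lower</sub> = g<sub>ph</sub> ± 0.15·(g<sub>br</sub> −
  g<sub>ph</sub>)** anchored at the well-center gray value, binarize,
  erode, keep the central patch, dilate, and report the patch area over
  the well circle.
* **Focus metrics** (`tenengrad()`, `mean_gray()`,
  `sweep_correlation()`): Tenengrad sharpness vs. mean gray over an
  annulus-displacement sweep, the evidence that background brightness
  alone indicates phase-contrast conditions.
* **Acquisition planning** (`plan_tiles()`, `focus_map()`,
  `assemble_mosaic()`): tile grids covering a circular well with
  overlaps, four-anchor plane autofocus, known-coordinate mosaic assembly
  with feathering, shading and histogram correction.
* **Synthetic optics** (`meniscus_model()`, `generate_bertrand_image()`,
  `generate_well_mosaic()`, `generate_calibration_pairs()`,
  `simulate_displacement_sweep()`): a seeded, byte-deterministic simulator
  of the meniscus-displaced annulus, used as ground truth for every test
  and benchmark — no microscope required.

## Worked example

Detect a known misalignment in a synthetic Bertrand image and map it to a
corrective LCD position:

```r
library(apcmicro)

truth <- bertrand_truth(offset = c(150, -60))       # full-resolution px
scene <- generate_bertrand_image(truth, meniscus_model(noise_sigma = 5),
                                 distractors = 2, seed = 7)
off <- detect_offset(scene$image,
                     phase_ring_center = truth$phase_ring_center)
off
#> Ring offset: delta_d = (30.40, -11.62) px at scale 0.2 (|delta_d| = 32.55 px)
```

The true offset is (150, −60) px at full resolution, i.e. (30, −12) at the
20% analysis scale; the detector recovers it to about half a pixel despite
noise and two reflection distractors. With a calibration model (here built
from the reference scaling factor 0.0113 mm per full-resolution px,
expressed at the analysis scale):

```r
model <- calibration_model(0.0113 / 0.2, c(0, 0))
map_offset_to_lcd(off, model)
#> corrective LCD position: (1.718, -0.657) mm
```

Quantify the phase-contrast area of a textured synthetic well whose
ground-truth fraction is 41.9%:

```r
gm <- generate_well_mosaic(0.419, texture = TRUE, seed = 11)
quantify_area(gm$image, gm$truth$well_center, gm$truth$well_radius)
#> Phase-contrast area: 42.5% of the well (radius 950 px at analysis scale 1)
#> Thresholds: g_ph = 73.2, g_br = 220.7 -> [t_lower, t_upper] = [51.0, 95.3]
```

And summarize a conventional-vs-adaptive comparison over three wells
(fractions in percent):

```r
s <- summarize_wells(c(5.0, 5.1, 5.0), c(42.7, 42.8, 40.3))
s$summary
#> # A tibble: 2 × 4
#>   statistic conventional adaptive ratio
#>   <chr>            <dbl>    <dbl> <dbl>
#> 1 mean            5.03      41.9  8.33
#> 2 sd              0.0471     1.16 0.201
```

The adaptive annulus restores phase contrast over ~42% of the well versus
~5% conventionally — an 8.3-fold gain.

A thin command-line wrapper around these functions ships in
`inst/scripts/apc.R` (`Rscript apc.R simulate|detect|benchmark|calibrate|map|quantify|metrics ...`).

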