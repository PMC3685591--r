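---
title: "Quantifying fractional-laser treatment coverage from skin thermograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fractional-laser treatment coverage from skin thermograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocov)
```

## The measurement problem

In fractional CO2 laser resurfacing an operator applies a scanner head
repeatedly across the treatment area.  Each application delivers a grid of
microbeams to one square footprint of skin; the footprint heats by roughly
2.5 °C above the pre-treatment skin temperature (about 33 °C) and, because
the thermal relaxation of the ablated columns is slow, stays visible to an
infrared camera for many minutes.  Freehand application is imperfect in two
opposite ways: footprints that fail to abut leave untreated skin, and
footprints placed on top of each other deliver a double dose, which is the
clinically harmful error.  A single post-treatment thermogram therefore
contains enough information to audit the procedure.

`thermocov` turns a thermogram (a matrix of surface temperatures in °C,
nominally 320 × 256 px from a photon-detector camera) into two numbers:

* **δ_o** — the percentage of the treated region `L_R` covered by **zero**
  footprints (undertreatment), and
* **δ_z** — the percentage of `L_R` covered by **two or more** footprints
  (double dose),

together with the geometry they derive from: the treated-region mask, the
common rotation angle of the pulse grid, and one rotated square `L_i` per
detected pulse.

Both errors are defined by per-pixel coverage counts over `L_R`: a pixel
with count 0 is uncovered, a pixel with count ≥ 2 is overlapping, and

```
δ_o = 100 · |{count = 0} ∩ L_R| / |L_R| ,   δ_z = 100 · |{count ≥ 2} ∩ L_R| / |L_R|.
```

For pairwise overlaps this is identical to the inclusion–exclusion count
`(|L_R| − Σ_i |L_i| + |L_Z|)/|L_R|` (with `L_Z` the overlap mask), and it
stays exact when three or more footprints superimpose.  The notional
definition of δ_z as "overlap area over itself" that a literal reading of
the published formula would give is degenerate (always 100 %); the verbal
definition — overlap area relative to the whole treated region — is what is
implemented.

## Stage one: segmenting the treated region

`extract_roi()` composes:

1. **Nearest-neighbour upsampling** to the working resolution (default
   480 × 640), which raises resolution without inventing new temperature
   values.
2. **Median filtering** (3 × 3) to reject impulsive detector noise.
3. **Grayscale opening** with a flat square structuring element
   (`se_radius_px`, default 80, i.e. a 161-px element) and a **difference
   image** `L_U = L_O − L_MED`.  The element is deliberately *larger than
   the whole treated field*: the opening then flattens the field away and
   returns the local background, so `|L_U|` is the temperature elevation
   above the surrounding skin, independent of the absolute skin
   temperature.  (With an element smaller than one footprint the opening
   reconstructs the footprints and the difference is ~0 everywhere — there
   is nothing to binarize.)  A `difference_polarity` switch selects the
   closing-based variant instead; both threshold `|L_U|`.
4. **Binarization** at the constant threshold `p_r` (strict `>`).  `p_r`
   is an offset in °C above the pre-treatment skin temperature.  If not
   set, it is chosen as 40 % of the robust range of `|L_U|` (its 99.5 %
   quantile minus its median): for a typical 2.5 °C elevation this lands
   near 1 °C.  The threshold is logged in every report; no single value is
   unequivocally correct (see the sweep below).
5. **Cluster selection**: a binary closing (`roi_bridge_px`, default 5)
   first bridges narrow cool gaps so that one treated field labels as one
   cluster; the largest 8-connected component is kept (ties broken by
   bounding-box position) and its interior holes are filled.  Hole filling
   matters: the uncovered area we want to *measure* is exactly the area
   binarization removes, so `L_R` must be the filled field, not only its
   above-threshold pixels.

All filters use edge replication (median) or clipped windows
(erosion/dilation), avoiding spurious cold borders.  The rank and
morphology filters are exact compiled implementations, so the opening is
anti-extensive and idempotent to machine precision and the median agrees
with a sort-and-pick oracle elementwise.

## Stage two: recovering the pulse geometry

The operator applies the head without rotating it, so all footprints share
one angle α\* and the grid is 90°-symmetric; α\* is reported in [0°, 90°).

* **Canny edges** of the median-filtered image, restricted to the dilated
  region of interest.  The hysteresis thresholds are quantiles
  (`canny_low` = 0.4, `canny_high` = 0.8) of the gradient magnitude inside
  the region, so they adapt to scene contrast; lowering the high threshold
  can only grow the edge set.
* **Radon transform** of the edge mask over angles sampled every
  `radon_angle_step_deg` (default 0.5°) on [0°, 90°).  Each edge pixel
  contributes one count to the bin `round(n·cos α + m·sin α)`, so the
  column mass equals the edge count exactly at every angle.  Collinear
  footprint edges concentrate into single bins when the projection runs
  along their direction; the angle score is the maximum single bin and α\*
  is the arg-max (smallest angle on ties).  A flat score profile raises an
  "angle not identifiable" error rather than returning noise.
* **Watershed segmentation** of the detrended temperature topography.
  The constant temperature component over the region is removed first
  (mean subtraction by default; a grayscale-opening background is the
  `"local"` alternative).  Markers are regional maxima that survive
  h-maxima suppression at `watershed_h` (default 0.3 °C) — sensor noise
  (σ ≈ 0.05 °C) and small ridges from slightly overlapping footprints do
  not seed basins, but genuine pulse apices (prominence ≳ 0.6 °C for a
  Gaussian-profiled beam) do.  The basins partition the region exactly.
* **Square approximation.**  Every kept basin becomes a `PulseArea`: a
  filled rotated square at the shared angle α\*.  Centers are the
  intensity-weighted centroids of each basin's upper half, refined by an
  iterative symmetric-window centroid with local plane subtraction — the
  diffusion warmth under the field tilts boundary basins and would
  otherwise bias centers toward the field interior; the test suite checks
  sub-2-pixel mean center recovery after refinement.  The side length is shared by
  all footprints because they come from one physical head: it is taken
  from `pulse_side_px` when known (the head geometry and camera optics fix
  it — in the paper's words, only the angle is unknown), and otherwise
  estimated as the median over basins of the square root of the upper-half
  core area.  Basins with area outside [0.25, 4] × the median are
  discarded as spurious and recorded.  A pixel belongs to a square iff its
  center lies inside the rotated boundary, half-open on the max edges, so
  abutting squares tile without artificial overlap.

`analyze_image()` finally clips each square to the binarized elevation
evidence (a fitted square only counts as dose where the skin is actually
elevated above `p_r`) and to the region of interest, counts coverage per
pixel, and emits a `coverage_report` with the exact integer pixel ledger
(`uncovered + single + multi = |L_R|`), the angle, the threshold used and
the uncovered/overlap masks.  The whole pipeline is deterministic.

Derotation by −α\* is available (`derotate()`, nearest-neighbour so masks
stay binary, invertible to Jaccard ≥ 0.95 for moderate angles) but the
pipeline does not need to resample the image: fitting rotated squares at
α\* is equivalent to equalising the rotation first and numerically cleaner.

## The threshold sweep

`threshold_sweep()` quantifies why footprint segmentation cannot rest on
binarization alone.  The treated region and fitted geometry are
established once at the reference configuration; each swept `p_r` then
re-binarizes the evidence the squares are clipped to.  Because the
binarized sets are nested in `p_r`, δ_o(`p_r`) is nondecreasing by
construction, and on realistic scenes — where the footprint interior has a
bell-shaped temperature profile — it grows almost linearly over the
mid-range of the elevation distribution (R² ≳ 0.95 for a linear fit).  A
swept value equal to the configuration's own threshold reproduces
`analyze_image()`'s numbers exactly.  The default sweep covers the 20–80 %
quantiles of the in-region elevation: the mid-range where the choice of
threshold is genuinely ambiguous.

## The synthetic thermogram generator

No patient thermograms are distributed, so `scene_grid()` /
`generate_scene()` produce test scenes with pixel-exact ground truth.  The
rendered elevation field is

* one **Gaussian-beam footprint** per pulse: the rotated square indicator
  convolved (analytically, as a product of normal-CDF differences) with an
  isotropic Gaussian of `beam_sigma_px` (default 5 px) — the bell-shaped
  fluence of a CO2 beam gives each footprint a warm apex and cooler edges;
* a **saturating composition** across pulses (`pmax`): skin temperature
  does not double where footprints overlap, so overlap leaves no direct
  thermal ridge and must be recovered geometrically, which is the honest
  difficulty of the problem;
* a broad **diffusion mound** under the whole field: `mound_amp_c`
  (default 1.5 °C) times a Gaussian blur (`mound_sigma_px` = 8) of the
  region indicator, emulating lateral heat conduction that keeps
  inter-pulse gaps warmer than untreated skin;
* **baseline 33 °C**, **elevation 2.5 °C**, i.i.d. Gaussian sensor noise
  (default σ = 0.05 °C), all seeded and bit-reproducible.

Ground truth uses the exact geometric squares (before beam blur and
noise): per-pulse masks, union, overlap (count ≥ 2), the region polygon,
and true δ_o/δ_z by direct pixel counting.  `generate_sequence()` renders
the approach to steady state as a first-order step response
`T(t) = T0 + E·(1 − e^{−t/τ})` with τ = 1.5 s (the skin settles within a
few seconds of the forcing; the closed form is exact in the generated
frames), and `check_analysis_window()` enforces the validity window for
real acquisitions: no sooner than 10 s after the last dose (closed
interval), no later than 180 s by default — early frames are still rising,
late frames blur by thermoregulation.

What the generator deliberately does **not** model: heat diffusion as a
PDE (the mound is a stationary stand-in), anatomy-shaped backgrounds,
motion, perspiration or hair artifacts, and emissivity/calibration errors.
Passing the synthetic suite therefore demonstrates the correctness of the
algorithmic chain — segmentation, angle recovery, footprint fitting,
counting — under the stated thermal model, not robustness to every
clinical confounder.

### Scene choices used by the tests

* *Standard scene*: 3 × 4 grid, side 30 px, pitch 34 px (4-px gaps),
  margin 2 px — true δ_o ≈ 22 %, δ_z = 0.  This mirrors the published
  situation where undertreatment dominates (their cohort mean was
  δ_o ≈ 18 %).
* *Overlap scene*: irregular column spacing (offsets 0/34/60/94) giving
  one 4-px overlap band per row — true δ_o ≈ 20 %, δ_z ≈ 2.8 %, matching
  the reported single-digit overlap regime.  Bands of 4 px are used
  rather than many 1-px slivers because a 1-px band sits below the
  rasterization sensitivity of the measurement (a half-pixel center error
  flips it on or off), which would test luck, not accuracy.
* *Tiling null case*: pitch = side (gap-free, overlap-free), sharp edges
  (`beam_sigma_px` = 1) and no mound — the scene isolates rasterization
  and fitting tolerance, and the errors reported on it stay within 3 %
  (δ_o) and 1 % (δ_z).
* The analysis of generator scenes passes `pulse_side_px = 30`, treating
  the footprint side as the hardware constant it is; the estimator fallback
  is exercised separately on plateau labels, where it is unbiased.

## Numerical choices and degenerate inputs

* Temperatures are validated into [0, 60] °C and must be finite; frames
  smaller than 8 × 8 are rejected.
* CSV stores `%.17g` (lossless for doubles); TIFF stores 32-bit IEEE
  floats (a minimal writer is included because the available TIFF writer
  only emits normalised integer samples), exact at single precision.
* Blank scenes raise "no treated region detected"; constant regions yield
  empty edge images with a warning; an empty or flat sinogram raises
  "angle not identifiable"; an empty marker set raises "no pulses
  detected"; every pipeline error is tagged with its stage.
* Angle ties break toward the smallest angle; component-size ties break
  toward the smallest bounding box; both make reports byte-reproducible.
* Problem sizes in the test-suite and acceptance script (480 × 640 frames,
  12-pulse grids, 20 angle scenes, 200 randomized metric configurations)
  keep a full run in the low minutes on one CPU while leaving every
  contract at full working resolution.

## Known limitations

* The side estimator (median √core-area) assumes footprints with a flat
  or plateau-like top; for strongly bell-shaped profiles it understates
  the side, which is why the hardware side should be supplied when known.
* Heavily merged footprints (overlap beyond ~half a side) have a single
  thermal apex and cannot be split by any intensity watershed; they are
  fitted as one footprint.
* δ_o and δ_z are relative to the *detected* region; if the field halo
  differs systematically from the true treated boundary (e.g. unusual
  emissivity at the field edge), both errors inherit a small bias.
* One treated field per image (the largest cluster); multi-field frames
  need to be cropped upstream.
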