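---
title: "Designing region-of-interest MV imaging apertures for intrafraction motion correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing region-of-interest MV imaging apertures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(mvroi)
```

## The problem

During frameless cranial stereotactic radiosurgery the patient can drift by
a few millimetres over a long arc delivery. The treatment beam itself can
image the patient: at any control point (gantry/couch combination) of the
arc, a megavoltage (MV) portal image on the EPID shows the anatomy in the
beam's-eye-view (BEV), and registering it against a reference DRR reveals
the in-plane displacement, from which a couch correction follows. Imaging
with the full open field at every control point, however, deposits
unnecessary dose. The idea implemented here is to shrink the imaging field
to a small control-point-specific region-of-interest (ROI) aperture chosen
so that registration stays accurate: most of the dose saving of a small
field, almost none of the accuracy loss.

`mvroi` implements that design loop end to end on a digital skull phantom:

1. **Phantom** (`generate_skull_phantom()`) — an ellipsoidal bony shell
   (~400 HU) filled with soft-tissue-equivalent material (36.1 HU), a 2 mm
   high-Z BB fiducial at isocenter, air-filled sinus-like cavities, and
   seeded random surface bumps so no view is rotationally degenerate.
2. **Projection** (`compute_drr()`) — Siddon ray tracing of the volume to
   any gantry/couch geometry; intensity is `exp(-path)` of the
   radiological path with `mu = mu_water (1 + HU/1000)`.
3. **Registration** (`register_translation()`) — translation-only
   maximization of joint-histogram mutual information (MI).
4. **Aperture search** (`build_imaging_plan()`) — thousands of random
   rectangles per BEV, scored by how well known grid shifts are recovered
   through them, the top 10% overlaid into a topographic map, and the
   imaging aperture cut from the map at a threshold level.
5. **Motion correction** (`simulate_delivery()`, `derive_couch_shift()`) —
   simulated EPID acquisitions under motion traces, displacement detection
   by anatomy registration or BB tracking, and the BEV-to-couch transform.

## Geometry and conventions

All room-frame quantities use the fixed couch axes (lateral, longitudinal,
vertical), with the isocenter at the origin. Gantry angles are on the
common Varian-IEC/IEC scale (0 = beam pointing down onto a supine
patient); couch angles are kept on the planning-system scale in which the
axial arc reads 0 — this is the scale the couch-shift matrix uses
directly. `couch_eclipse_to_iec()` converts for IEC displays (axial = 180).

The BEV basis is derived from the couch-shift transform itself:

$$\begin{aligned}
\Delta \mathrm{Lat} &= \cos\phi \, d_x \cos\theta - \sin\phi \, d_y \\
\Delta \mathrm{Lng} &= \sin\phi \, d_x \cos\theta + \cos\phi \, d_y \\
\Delta \mathrm{Vrt} &= d_x \sin\theta
\end{aligned}$$

with $(d_x, d_y)$ the BEV displacement at the isocenter plane, $\theta$
the gantry and $\phi$ the couch angle. The matrix has orthonormal columns,
so $\lVert(\Delta \mathrm{Lat}, \Delta \mathrm{Lng}, \Delta
\mathrm{Vrt})\rVert = \sqrt{d_x^2 + d_y^2}$ identically: one planar view
recovers exactly the motion component visible in that view, never the
component along the beam. Projecting a room offset into the BEV and
transforming back reproduces the visible component to machine precision —
this closure is asserted in the test suite over random geometries.

The three-arc cranial geometry (`table1_arcs()`) holds one full axial arc
and two 184.9-degree partial arcs with the couch at ±45; the partial arcs
both cross gantry zero. Control points are placed every `spacing` degrees
from each arc's start angle (no snapping of the 180.1/179.9 endpoints),
giving 72 + 37 + 37 points at 5-degree spacing.

## The MI registration engine

Registration maximizes the joint-histogram MI (50 equal-width bins per
image, each image binned over its own range) over in-plane translations.
Design choices that matter:

* **Histogram smoothing.** Each sample spreads linearly over the two
  adjacent bins on both axes, so MI varies smoothly between pixels.
* **Deterministic search.** An integer-pixel coarse grid (stride 2, then
  1) inside the search bound, followed by step-halving pattern refinement
  down to 0.01 mm. No stochastic optimizer: identical inputs always give
  identical answers.
* **Pixel-locking control.** Sampled joint-histogram MI carries a roughly
  1-pixel-periodic perturbation that biases subpixel optima by up to
  ~0.1 px. The accurate mode therefore evaluates the final refinement
  stages on the half-pixel supersampled grid, with both images resampled
  by interpolating cubic B-splines; the sample set then holds both phases
  of the locking term in equal measure and its fundamental cancels.
  Measured recovery error on information-rich crops is 0.02–0.04 mm at
  0.5–0.8 mm detector sampling.
* **Shift-invariant sample window.** Refinement samples only pixels whose
  fixed and moving lookups stay inside the interpolation support for the
  whole refinement neighbourhood around the coarse optimum, so the MI
  objective cannot jump when samples drop off an edge.
* **Two speed grades.** Bulk aperture scoring uses bilinear resampling and
  caps MI evaluations at ~1200 pixel samples per image (row/column
  striding); final error measurements use the accurate cubic mode on the
  full crop. Ground-truth shifted images are always produced by windowed
  Fourier translation, so the oracle's interpolation model is independent
  of either resampler.

A degenerate crop — one without genuine contrast — is reported as
`converged = FALSE` rather than as a shift; the aperture search treats
such apertures as invalid (infinite score).

## Aperture search parameters

Per control point, `n` rectangles are drawn with area log-uniform over
0.375–37.5 cm² (even coverage of small and large apertures on the log
scale), aspect ratio uniform in [1/3, 3], and center uniform over the
positions that keep the rectangle inside the 22 × 22 cm² open field. Each
aperture is scored by registering the aperture crop of the grid-shifted
DRR back to the unshifted crop; one Fourier-shifted image per grid point
is shared across all apertures of a BEV. The ranking scalar is
`mean(|error|) + SD(error)` — the simplest scalarization that penalizes
both bias and spread; the `floor(0.1 n)` best (ties broken by smaller
area, then sampling order) are overlaid into the topographic map, and the
imaging aperture is the bounding rectangle of the largest connected
component of the superlevel set at the threshold (60% of the map maximum
by default). Higher thresholds give smaller, nested apertures.

Good/bad labels follow the error-range definition: an aperture (≥ 4 cm²)
is *good* when the 95th–5th percentile range of |error| stays below
0.1 mm and the mean signed error within ±0.1 mm on both axes, *bad* when
the range exceeds 1 mm. Two information metrics characterize the anatomy
inside an aperture: the mean MI drop-off of the 121-element shift surface
(`mi_mean_difference()`), and the variance of the sum-normalized
eight-bin gradient polar histogram (`polar_variance()`, 0 for isotropic
directional content up to 7/64 for fully unidirectional content). On the
synthetic skull, good apertures show a larger MI drop-off and a smaller
normalized polar variance than bad ones — the orderings the physical
study reported — and these orderings, not the phantom-dependent
magnitudes, are what the acceptance suite asserts.

## Study conditions and problem sizes

The package defaults encode two scales:

* **Reference scale** (function defaults): 0.625 mm phantom voxels, the
  0.224 mm isocenter-plane detector sampling of a 0.336 mm panel at
  SID 1500, 3000 apertures per control point, a 10 × 10 scoring grid over
  ±2 mm.
* **Desk scale** (`run_config()` defaults, acceptance script, heavy
  tests): 1 mm phantom voxels (the BB must span at least two voxels),
  0.6 mm detector sampling, 15-degree control-point spacing (50 control
  points over the three arcs), 300 apertures per control point, a 3 × 3
  scoring grid over ±2 mm. At this scale a full plan build plus the
  ±2.5 mm 11 × 11 validation study completes in roughly ten minutes on
  one CPU. 0.6 mm sampling is deliberately not a divisor of the 0.5 mm
  validation-grid step, so the applied shifts genuinely exercise the
  subpixel path.

The delivery simulation is open-loop: at each control point the phantom
sits at the motion trace's true offset, an EPID image is simulated (the
DRR of the rigidly translated volume, BB included — reference DRRs have
the BB region replaced by fill material beforehand), the displacement is
detected, and no correction is fed back, so detections can be compared
directly against the known trace and between methods. BB tracking — a
morphological top-hat to remove structures larger than the fiducial,
candidate vetting by component size relative to each candidate's own
local peak, then a disk-matched convolution and subpixel centroid — is
the gold standard; anatomy registration is the method under test.

## What the synthetic phantom does and does not show

The generator reproduces the statistical structure the registration
problem needs: bony edges of varying orientation and curvature,
featureless interior regions, air cavities, and a fiducial that dominates
any disk-matched response. It is noise-free by default (Gaussian HU noise
and Poisson-like EPID noise are available as options), its shell is
smooth apart from the seeded bumps, and it contains no mandible, no fine
trabecular texture, and no EPID panel physics (sag, glare, spectral
response). Passing tests therefore demonstrate the internal consistency
and accuracy of the method under idealized imaging, not clinical
performance: on real images the contrast is lower and the noise higher,
which is precisely why the physical study's absolute numbers (dose
reductions, per-plan error magnitudes) are out of scope here, while
structural claims — sub-0.1 mm grid-shift recovery through designed
apertures, sub-mm closed-loop medians, metric orderings between good and
bad apertures — are reproduced.

## Numerical choices and degenerate inputs

* Tolerances: registration refinement 0.01 mm (accurate mode) / 0.02 mm
  (bulk scoring); Siddon versus a dense ray-marching oracle agrees to
  0.05% on skull-crossing rays.
* Tie-breaks: equal aperture scores resolve to the smaller area, then to
  sampling order; the threshold aperture uses the largest connected
  component of the superlevel set.
* Degenerate inputs: constant images are refused by preprocessing (with a
  warning) and by registration (failure flag); apertures covering no
  detector pixels, empty superlevel sets, and BB-overlapping sampling
  regions are errors; a control point whose search fails falls back to
  the open field with a warning.
* Determinism: every stochastic step takes an explicit seed
  (`withr::with_seed`); plans re-built from the same seed serialize to
  byte-identical JSON, and the per-control-point search seed is
  `seed + cp` so control points are independent.

## Known limitations

Translation-only registration (couch yaw is assumed controlled);
rectangles only (no conformal MLC shapes); no scatter, spectrum, or
detector response in the projector; single-image 2D detection cannot see
motion along the beam axis (the couch transform makes this explicit); the
partial-arc control-point count follows the uniform stepping rule, which
matches the axial arc's published 72 points but yields 37 rather than 38
per partial arc.

## A worked desk-scale run

```{r pipeline}
cfg <- run_config(seed = 7)
res <- run_pipeline(cfg)

glance(res$plan)          # aperture sizes across the 50 control points
res$study$summary         # grid-shift registration errors, p99 in mm
glance(res$errors)        # anatomy-vs-BB medians under the sudden shift
autoplot(res$errors)
```

The same stages are available piecemeal — `generate_skull_phantom()`,
`control_points_from_arcs()`, `build_imaging_plan()`,
`registration_error_study()`, `simulate_delivery()`, `evaluate_errors()` —
and through the thin command-line wrapper in `inst/cli/mvroi`.
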