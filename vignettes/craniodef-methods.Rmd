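---
title: "Measuring brain deformation after decompressive craniectomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring brain deformation after decompressive craniectomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniodef)
```

## The measurement problem

After a decompressive craniectomy (DC) the brain herniates outward
through the skull opening. Two scalar outputs of the operation are of
clinical interest: the maximum outward displacement of the brain
surface, `dy_max`, and the herniated volume, `dV`. The classical Flint
measure reads a single distance off one post-operative CT slice — from
the craniectomy baseline to the brain surface — and therefore (a)
ignores the pre-operative brain shape, overestimating the true
displacement, and (b) is very sensitive to where the baseline falls on
a bifrontal opening, where a small change in opening width moves the
baseline substantially.

`craniodef` measures displacement as a *difference of surfaces*:
`dy = y_post - y_pre` along rays normal to the craniectomy baseline,
evaluated at stations covering the opening on every slice it crosses.
The pre-operative brain surface is defined as the inner table of the
skull: a patient needing DC has raised intracranial pressure, so the
brain is pressed against it. This convention makes the pre-op surface
recoverable from bone alone, which is robust at CT contrast.

## Pipeline and model assumptions

The chain is: gantry-tilt correction, skull thresholding, rigid
registration of the pre-op scan onto the post-op scan (skull as fixed
reference), brain segmentation of the post-op scan, baseline fitting,
then the measures. The assumptions that matter:

* **Rigid skull.** Registration is 6 degrees of freedom only; the
  skull (minus the removed flap) is unchanged by the operation.
  Deformable registration is deliberately out of scope: on thick-slice
  clinical CT it is known to behave poorly.
* **Brain at the inner table pre-operatively.** If the pre-op brain
  genuinely sags away from the skull, `y_pre` is underestimated and
  `dy` overestimated; the phantom's `brain_margin` parameter exists to
  study exactly this deviation.
* **Axial slice geometry.** The displacement field and the Flint
  measure are evaluated slice-wise (the clinical workflow is slice
  oriented); the baseline normal must therefore have a usable in-plane
  component, which holds for both bifrontal and lateral openings.

## The geometric measures

`locate_baseline()` finds the removed bone (`pre & !post` of the
registered skull masks), extracts the rim as midpoints of
aperture/skull voxel face pairs (sub-voxel placement of the opening
wall), fits a plane by least squares and orients its normal away from
the brain. Height and width are rim extents along the two principal
in-plane axes; the per-slice chords of the opening are retained.

`displacement_field()` lays stations along each slice's chord at the
in-plane voxel spacing and casts rays along the outward in-plane
normal. `y_pre` and `y_post` are signed distances to the outermost
crossing of the respective brain-edge polygon (the outermost crossing
handles overhanging bulges); stations with no crossing in either scan
are excluded and counted. `dy_max` is the field maximum, ties broken
toward the station nearest the aperture centroid, so the result is
deterministic.

`herniated_volume()` is the voxel-count difference of the brain masks
times the voxel volume. Negative values are not clipped — they are
flagged, because they diagnose registration/segmentation failure or
genuine pre-op volume loss (e.g. haematoma evacuation).

Two area estimators are provided. `area_height_width()` is the
rectangular product of the opening's maximal extents; it exceeds the
inscribed-ellipse area by exactly `4 / pi = 1.27`. `area_mesh()`
triangulates the pre-op skull iso-surface (marching tetrahedra over a
lightly smoothed mask) and sums outer-table triangles over the
removed-bone footprint; it measures the curved opening area and is
flagged degenerate rather than trusted blindly, reflecting the known
unreliability of mesh differencing on clinical data.

Two closed-form models link the measures: the parabolic cap
`dV = pi r^2 dy_max / 2` (for a circular opening of radius `r`; at
`r = 35` mm and `dy_max = 25` mm it gives 48,106 mm³, i.e. ~48 ml) and
a cylindrical model `dV = pi (r_eq - e)^2 dy_max` whose edge
restriction `e` is left as a free parameter — the pure cylinder is
exactly twice the parabolic cap and systematically overestimates.

## Numerical choices

* **Interpolation.** Intensities are resampled with a Catmull–Rom
  cubic kernel (interpolating, reproduces linear ramps exactly); masks
  travel as trilinearly interpolated indicators thresholded at 0.5.
  The latter matters: nearest-neighbour transport adds half-voxel
  surface jitter whose fluctuation would dominate `dV`, a small
  difference between two ~1000 ml quantities.
* **Registration metric.** Mean squared difference between
  Gaussian-smoothed (3 mm) mask indicators, sampled at up to 6000
  fixed-grid points near the fixed skull surface, with the worst 5% of
  residuals trimmed so that bone present in only one scan — the
  removed flap — cannot steer the fit. Optimised by Nelder–Mead from
  five deterministic starts (centroid alignment ± 8° rotations),
  followed by a polish phase; the recorded metric trace is
  non-increasing. On phantoms this recovers a planted 5° / 10 mm
  misalignment to better than 0.1° / 0.1 mm; the package asserts
  0.5° / 0.5 mm.
* **Skull threshold.** Midpoint of the two non-air intensity modes via
  deterministic 2-means (quartile initialisation); overridable in the
  config.
* **Segmentation defaults.** Window 400 HU at level 40 HU; statistical
  region merging at granularity `Q = 25`; brain band −150..250 HU;
  contour cleanup = hole filling plus a radius-2 morphological opening
  constrained to stay within one voxel of the filled input. The
  opening-only choice is deliberate: a closing pads concave staircase
  corners at the herniation apex and would bias `dy_max` upward by
  1–2 voxels.
* **Edge tracing.** Per-slice 0.5-level contours of the mask after a
  0.8-voxel in-plane Gaussian. The raw 0.5 contour of a binary grid is
  a staircase; taking a field maximum along a staircase inherits its
  half-voxel teeth, so the sub-voxel smoothing is what keeps `dy_max`
  within one slice spacing.
* **Degenerate inputs.** Empty skull masks, missing craniectomy
  (`pre == post`), collapsed contours, no-crossing stations and
  negative volumes all have defined, flagged behaviours rather than
  exceptions mid-cohort; `run_case()` records per-stage failures and
  emits partial summaries with missing-value markers.

## What the phantom emulates — and what it does not

`phantom_spec()` / `generate_phantom()` build an ellipsoidal skull
shell (default outer radius 72 mm with axis ratios 1 : 1.25 : 0.9,
6 mm thick) filled by brain to the inner table, with an elliptical
aperture on the anterior midline (bifrontal) or a lateral convexity
(unilateral). The post-op brain is the pre-op brain sheared outward
along the aperture axis by a parabolic or spherical-cap profile, so
the planted `dy_max` and the analytic bulge integral
(`pi a b h / 2` for the parabolic profile) are exact ground truth by
construction. Acquisition nuisances are additive Gaussian noise
(default 15 HU against a 660 HU bone/brain contrast), a planted rigid
misalignment of the pre-op frame, gantry-tilt shear of the post-op
stack, and anisotropic default spacing (0.5 × 0.5 × 5 mm) emulating
thick-slice emergency CT.

The phantom does **not** emulate: anatomical brain shape, CSF or
haematoma compartments, partial-volume intensity gradients,
beam-hardening or metal artefacts, or non-rigid brain shift away from
the herniation. Passing the phantom suite therefore demonstrates that
the geometry and arithmetic of the chain are correct at clinical voxel
sizes — not that segmentation parameters transfer untouched to real
scans, where the window/level, SRM granularity and brain band are the
knobs a user should expect to adjust.

Test problem sizes are chosen for fast, deterministic suites: most
component tests run on ~90³ grids at 2–3 mm spacing, the end-to-end
recovery on a 128³ grid at 1.65 mm, and the statistics layer on
planted summary tables; the same code paths scale to clinical
resolutions unchanged.

## Design decisions on genuinely open points

* **Baseline as a fitted 3-D plane.** The rim of a real (especially
  bifrontal) opening is not planar; a least-squares plane is the
  natural 3-D extension of the slice-wise baseline and makes the
  outward normal well defined. The per-slice chords are kept verbatim
  for the Flint comparison.
* **`dV` as whole-volume difference.** The mask difference integrates
  all brain-volume change, not only the part inside the herniation;
  with the phantom's shear construction the two coincide. On clinical
  data other changes (evacuated haematoma, ventricular change)
  contribute — hence the sign flag instead of silent clipping.
* **Registration metric choice.** Only the use of a rigid,
  skull-referenced registration is prescribed by the method;
  the smoothed-indicator SSD used here is one defensible choice and is
  accepted through its recovery oracle, not through metric values.
* **Wirtz-style cylinder.** The exact published formula is not
  reproduced here; the model is implemented as described qualitatively
  — cylindrical expansion with an edge-restriction annulus — with the
  restriction exposed as a parameter instead of fixed.
* **Gantry-tilt model.** Correction is the conventional per-slice
  in-plane shear `k * slice_spacing * tan(tilt)`, applied before
  registration and validated self-consistently (shear, then correct,
  recovers the original to interpolation tolerance).

## Known limitations

* Slice-wise displacement requires the baseline normal not to be
  parallel to the slice axis; a purely axial opening (e.g. vertex
  craniectomy) would need a different station layout.
* `dy_max` is a maximum over ~10³ noisy stations and carries a small
  positive bias at coarse spacing; it is specified only to one slice
  spacing.
* `area_mesh()` depends on mesh quality; it is reported with a
  degeneracy flag and the rectangular estimate remains the primary
  area measure.
* The statistics layer implements exactly the comparisons used in the
  measurement study (Pearson, Welch, multiple `R`, box summaries); it
  performs no multiple-testing correction, matching that analysis.
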