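# craniodef

Quantifying brain deformation after decompressive craniectomy from
paired CT volumes.

## The problem

Decompressive craniectomy (DC) removes a section of skull — either a
bifrontal plate across the anterior midline or a unilateral plate over
one lateral convexity — so that a swollen brain can expand outward
instead of raising intracranial pressure. How much the brain actually
herniates through the opening (the external cerebral herniation, ECH)
is a candidate marker for comparing the two operations, but the
classical single-slice measure (the Flint method) ignores the pre-operative
brain shape and is unstable for bifrontal openings.

`craniodef` implements an improved, automatable measurement chain for
neurosurgical imaging researchers:

1. **Gantry-tilt correction** of sheared slice stacks.
2. **Skull isolation** by thresholding, and **rigid registration** of
   the pre-op scan to the post-op scan using the skull as the fixed
   reference.
3. **Brain segmentation**: window/level accentuation, statistical
   region merging, a brain-band region threshold, and morphological
   contour cleanup, slice by slice. The pre-op brain surface is taken
   as the inner table of the skull (under raised ICP the brain is
   pressed against it).
4. **Deformation measures**: with the craniectomy baseline fitted to
   the rim of the opening, rays normal to the baseline give the
   displacement field

   `Δy = y_post − y_pre`

   at every station and slice, with its maximum `Δy_max`; the
   herniated volume `ΔV` is the difference of pre- and post-op brain
   mask volumes; the craniectomy area is estimated both as
   `height × width` and from the skull surface mesh. The Flint
   measure `y_Flint` is computed alongside for comparison (it equals
   `y_post` alone, hence never undershoots `Δy_max`).
5. **Geometric models**: the parabolic-cap law for a circular opening
   of radius `r`,

   `ΔV = π r² Δy_max / 2`,

   and a cylindrical model with an edge-restriction annulus.
6. **Statistics**: Pearson correlations, Welch's unequal-variance
   two-tailed t test, multiple regression `R`, and box summaries with
   1.5 IQR whiskers.

Because no clinical scans ship with the package, a **synthetic head
phantom** generator produces pre/post volume pairs — ellipsoidal skull
shell, brain at the inner table, elliptical aperture, parabolic or
spherical-cap bulge of known height, noise, planted rigid misalignment
and gantry tilt — with exact analytic ground truth for every measure.

## Worked example

```r
library(craniodef)

# a unilateral craniectomy phantom: 70 mm circular opening (r = 35 mm),
# parabolic herniation peaking at 25 mm, planted 2 deg / 5 mm misalignment
spec <- phantom_spec(
  skull_outer_radius = 66, axis_ratios = c(1, 1.2, 0.88),
  aperture_location = "unilateral",
  aperture_height = 70, aperture_width = 70,
  bulge_height = 25, noise_sd = 0,
  misalignment = rigid_from_euler(c(0, 0, 2), center = c(80, 90, 60),
                                  translation = c(4, 3, -2)),
  voxel_spacing = c(2, 2, 2.5), seed = 7)
ph <- generate_phantom(spec)

res <- run_case(ph$pre, ph$post, location = "unilateral", case_id = "demo")
res$summary
#>   case_id   location dy_max_mm dV_ml y_flint_mm area_hw_mm2 area_mesh_mm2 flags
#> 1    demo unilateral  26.00015 48.66   29.20795    5140.169      4446.821
#>   status
#> 1      0
```

Reading the row: the pipeline recovers the planted 25 mm maximum
displacement to within one slice spacing (26.0 mm) and the analytic
herniated volume `π·35²·25/2 = 48.1 ml` to within 1.2% (48.7 ml). The
Flint measure (29.2 mm) overestimates the true displacement, as it
must when the pre-op brain fills the skull. The rectangular area
estimate (5140 mm²) exceeds the mesh-based one (4447 mm²), the same
systematic ordering reported for the two estimators on clinical data.

The closed-form model check:

```r
parabolic_cap_volume(r = 35, dy_max = 25)
#> [1] 48105.64        # mm^3, i.e. ~48 ml
```

Cohorts are processed from a manifest (`case_id, pre_path, post_path,
location`) with `run_cohort()`, which adds the Pearson / Welch /
regression / box-plot comparison layer, or from the shell via
`inst/cli/craniodef.R` (subcommands `phantom`, `register`, `measure`,
`model`, `compare`, `run`).

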