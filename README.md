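# pedplan

Deterministic pedicle screw planning and Gertzbein–Robbins grading on
labeled vertebral CT volumes.

Spinal internal fixation anchors screws through the pedicles — the narrow
bony bridges between a vertebra's posterior elements and its body. Planning
a screw means choosing its dimensions (length `L`, diameter `D`, which
correlate with pullout force) and its trajectory (entry point and direction,
which decide whether the screw stays inside bone). `pedplan` implements the
deterministic core of an automated planner for users who study such
planners: given a pseudo-CT intensity volume and a co-registered anatomical
label map, it places, sizes and scores screws under explicit geometric
rules, grades arbitrary screw poses by breach depth, and runs the
statistics used to compare planned and freehand cohorts. A parametric
vertebra phantom generator with exact analytic ground truth stands in for
clinical data, so every stage is testable end to end.

## The rules at the core

For each pedicle of width `W` (the minimum caliper diameter of the corridor
cross-section) the planner selects, from a discrete implant catalog
(defaults: `L` ∈ 30–65 mm by 5, `D` ∈ 5–7.5 mm by 0.5):

* the **longest** length with the tip not beyond the anterior vertebral
  surface (`L <= depth_to_anterior`),
* the **thickest** diameter with `D <= 0.9 W` and at least 1 mm of bone
  between the screw surface and the outer surface of the medial and
  inferior pedicle walls,
* subject to never touching the superior/inferior endplates and to full
  bone containment of the (dilated) screw cylinder.

Among feasible candidates — an exhaustive entry × angle grid around the
pedicle axis — the planner maximizes a pullout-force proxy

```
pof_proxy = max(bmd_mean_hu, 1) * pi * D * L
```

where `bmd_mean_hu` is the mean CT intensity inside the screw cylinder, a
surrogate of bone mineral density along the trajectory. Placements are
graded on the Gertzbein–Robbins scale from the maximum distance by which
the screw surface protrudes outside the bone envelope: A — no breach
(below sampling resolution), B — < 2 mm, C — < 4 mm, D — < 6 mm,
E — ≥ 6 mm.

## Worked example

```r
library(pedplan)

ph <- make_phantom(phantom_spec())     # segmented vertebra, W = 8 mm corridors
cfg <- plan_config(transverse_range_deg = 9, transverse_step_deg = 3,
                   sagittal_range_deg = 6, sagittal_step_deg = 3,
                   entry_step_mm = 2)
plans <- plan_vertebra(ph$volume, ph$labels, config = cfg)
plans
#> <screw_plan> side L: 45 x 6.0 mm screw (W = 7.71 mm, 315 candidates)
#>   bmd 250.3 HU, pof proxy 212270; clearances medial 1.07 / inferior 2.05 mm
#> <screw_plan> side R: 40 x 6.5 mm screw (W = 7.71 mm, 315 candidates)
#>   bmd 253.7 HU, pof proxy 207247; clearances medial 2.07 / inferior 1.57 mm

grade_screw(plans$L$screw, ph$labels)
#> <gr_result> grade A (breach 0.00 mm)
```

Reading the output: the measured corridor width is 7.71 mm (truth: 8 mm, a
sub-voxel voxelization error), so the 90% rule caps the diameter at
6.94 mm; the left screw takes 45 × 6.0 mm because the longer length beats
the thicker 40 × 6.5 mm alternative on the pullout proxy, while the right
side — whose depth along its best trajectory is slightly shorter — takes
40 × 6.5 mm. Both keep ≥ 1 mm of medial/inferior wall clearance and grade A
on their own label map. `tidy(plans)` returns the same as a tibble;
`autoplot(reslice_along_axis(ph$volume, plans$L$screw))` shows the
screw-axis cross-sections used for visual audit.

The statistics layer reproduces a published clinical comparison of 208
AI-planned versus 208 freehand placements shipped as a plain-text fixture:

```r
summarize_grades(published_screw_grades())
#> Grade-A proportion by side:
#>   ai         L   94/104  90.38%
#>   ai         R   83/104  79.81%
#>   freehand   L   73/104  70.19%
#>   freehand   R   62/104  59.62%
#> Overall:
#>   ai            177/208  85.10%
#>   freehand      135/208  64.90%

fisher_exact_2x2(matrix(c(177, 135, 31, 73), 2, 2))
#> Fisher's exact test (2x2): p = 2.738e-06
```

A thin CLI (`inst/cli/pedplan.R`) exposes the same pipeline as
`phantom | plan | grade | compare` subcommands over NIfTI/JSON/CSV files.

## Documentation

The methods vignette (`vignettes/pedicle-screw-planning.Rmd`) describes the
model and its assumptions, the measurement conventions (wall clearance to
the outer wall surface, the entry-funnel exclusion in grading, the grade-A
tolerance), what the phantom generator does and does not emulate, and the
package's known limitations.
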