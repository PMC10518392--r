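---
title: "Geometric pedicle screw planning and Gertzbein-Robbins grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric pedicle screw planning and Gertzbein-Robbins grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedplan)
```

## The problem

Thoracolumbar internal fixation anchors a screw through each pedicle — the
narrow bony bridge between a vertebra's posterior elements and its body —
into the vertebral body. Two decisions dominate the plan: the screw's
*dimensions* (length and diameter, which correlate positively with pullout
force) and its *trajectory* (entry point and direction, which decide whether
the screw stays inside bone). Surgeons traditionally make both decisions
freehand from preoperative CT; planning software instead derives them from a
segmented CT volume under explicit geometric rules.

`pedplan` implements that deterministic planning core as an open geometric
engine. Given a co-registered intensity volume and anatomical label map, it:

1. measures the quantities the placement rules consume (pedicle axis and
   width, entry region, depth to the anterior cortex, wall clearances);
2. enumerates and sizes candidate screws under the placement constraints and
   returns the candidate maximizing a pullout-force proxy;
3. grades any screw pose on the Gertzbein–Robbins (GR) scale from its breach
   depth;
4. runs the group-comparison statistics (paired *t* on screw dimensions,
   Fisher's exact test on grade-A proportions) used to evaluate such planners
   against freehand cohorts.

Because no suitable public dataset of segmented vertebrae exists, the package
ships a parametric vertebra phantom generator with exact analytic ground
truth; every downstream stage is validated against it.

## Placement rules

For each pedicle the planner enforces, in this order:

* **Length**: the longest catalog length not exceeding the distance from the
  entry point to the outer anterior surface of the vertebral body (the
  "vertebral front end"), measured by ray casting through the label map.
  Overrunning the anterior cortex is a hard constraint, not a penalty.
* **Diameter**: the thickest catalog diameter that is (a) at most 90% of the
  measured pedicle width `W` and (b) keeps at least `margin_mm` (default
  1 mm) of bone between the screw surface and the outer bone surface of the
  medial and inferior pedicle walls — the walls facing the spinal canal and
  the exiting nerve root. Superior and lateral walls are governed by the
  containment filter below rather than by an explicit margin.
* **Endplates**: the screw cylinder may not touch the superior or inferior
  endplate labels.
* **Containment**: every voxel center inside the screw cylinder dilated by
  half a voxel diagonal (beyond the entry funnel) must carry a bone label.
  This single filter is what makes a feasible plan provably breach-free at
  the sampling resolution of the grading module, including against walls
  that carry no explicit margin; it also makes the planner conservative
  about tips grazing the curved anterior cortex.

The wall-clearance convention deserves a note. The safety margin is measured
from the cylinder surface through the bone of the wall to the first
non-bone sample — i.e., to the *outer* surface of the wall, beyond which the
structure at risk lies. With this reading the 90% width rule is the binding
diameter rule for anatomically walled pedicles, while for a bare corridor
with no wall the clearance reduces to the textbook annulus `(W - d) / 2`.
Measuring instead to the corridor label's edge would make the 1 mm margin
dominate everywhere (`d <= W - 2`) and the 90% rule vacuous.

## Trajectory search and scoring

The planning objective -- the trajectory with the highest bone density
and pullout force -- is
operationalized as an exhaustive, fully deterministic search:

* entry candidates: voxel centers of the posterior entry-disc label,
  subsampled on a `entry_step_mm` grid (default 1 mm);
* directions: a transverse × sagittal angle grid about the estimated
  pedicle axis (defaults ±15° × ±9°, 3° steps);
* each candidate is sized maximally, filtered by the constraints, and scored
  by `pof_proxy = max(bmd_mean_hu, 1) * pi * D * L`, where `bmd_mean_hu` is
  the mean intensity inside the screw cylinder (a CT surrogate of bone
  mineral density along the trajectory) and `pi * D * L` is the
  thread-bearing lateral surface. The proxy's only contractual property is
  strict monotonicity in density, diameter and length; it is a declared
  stand-in for biomechanical pullout models, not a calibrated force in
  newtons. The clamp at 1 HU keeps the proxy positive and monotone even in
  implausibly radiolucent bone.

Ties break deterministically: higher mean density, then smaller angular
deviation from the pedicle axis, then entry-point order. Two runs on the
same inputs return bit-identical plans.

The per-candidate hierarchy is "longest first, then thickest": length is
fixed by the anterior rule before diameters are tried. A candidate whose
maximal sizing fails containment is dropped rather than re-sized, since
another candidate with a slightly different entry or angle almost always
dominates it; the exhaustive search makes this safe.

## Gertzbein–Robbins grading

`breach_depth()` samples the screw's lateral surface and tip cap at
`surface_step_mm` (default 0.3 mm) and, for every sample outside the union
of bone labels, computes the exact distance to the nearest bone voxel
center (an exact Euclidean distance transform plus a bounded local search,
in compiled code). The maximum such distance is the breach depth, and the
grade bands follow the clinical scale with half-open boundaries:
A: depth ≤ ε; B: < 2 mm; C: [2, 4); D: [4, 6); E: ≥ 6 mm. The published
scale writes "<4, <6, >6", leaving the exact boundaries ambiguous; the
half-open-upward convention here is declared, not inferred.

Three conventions matter:

* **ε (grade-A tolerance)** defaults to half the maximum voxel spacing
  (0.3125 mm at the default 0.625 mm grid): surface sampling against a
  voxelized label map cannot resolve breaches below that.
* **Bone union**: breach is measured against *all* bone labels, so a screw
  passing from the pedicle into the vertebral body is not a breach —
  matching the clinical notion of a cortical breach.
* **Entry funnel**: lateral-surface samples within one screw diameter past
  the first bone contact along the axis are excluded. Clinical grading
  evaluates the intraosseous tract; without the exclusion, any oblique
  entry through a flat posterior surface would read a spurious breach of up
  to `r * sin(angle)` at the mouth. The tip cap is always graded.
* Distances are measured to the nearest bone voxel *center*, not to an
  interpolated surface; the accepted half-voxel bias is covered by ε and by
  the 0.2 mm oracle tolerance in the test suite.

## The phantom generator

`make_phantom()` builds a segmented lumbar-like vertebra from simple solids
chosen so that every placement rule has an exact analytic counterpart:

* vertebral body: an elliptic cylinder (default 36 × 30 × 28 mm) with a
  cortical shell and endplate slabs (1.25 mm);
* pedicles: elliptic corridors (width `W`, default 8 mm; height `W + 2`;
  free length 12 mm) wrapped in a cortical wall ring, converging toward the
  body at a transverse angle (default 10°, capped below 45° — severely
  scoliotic geometry is out of scope);
* posterior elements: a bone slab behind the pedicle mouths;
* entry regions: 3 mm-radius discs on the posterior surface where the
  extended pedicle axes exit, mirroring how planning software restricts the
  entry to a circular region at the facet/transverse-process junction.

The corridor tube is deliberately carved a few millimetres past its
attachment into the body, following the local slope of the body ellipse, so
the pedicle label is a complete elliptic tube with flat caps; without the
carve, the oblique junction leaves crescent-shaped label slivers that bias
axis and width estimation by several degrees and fractions of a millimetre.

Intensities are compartment constants (trabecular 250 HU, cortical 900 HU,
background −400 HU) plus i.i.d. Gaussian noise (sd 30 HU), seeded and
reproducible. The default voxel spacing is 0.625 mm isotropic, a standard
thin-slice CT protocol. This is emphatically *not* a CT simulation: there is
no beam hardening, no partial-volume blur, no metal artifact, and the
segmentation is perfect by construction. Passing tests therefore demonstrate
the geometric engine's correctness given a segmentation, not robustness to
real scanner physics or to segmentation error.

Cohorts (`make_cohort()`) draw spec fields uniformly from ranges; the
default pedicle-width range 7–13 mm reflects typical adult lumbar pedicles
(published anatomical series put most lumbar widths in that band). These
are fixture choices, not values taken from any single dataset. Unless
overridden, the corridor height tracks the drawn width (+2 mm) so that the
transverse width is always the limiting dimension, as in lumbar anatomy.
`perturb_screw()` emulates freehand deviation with isotropic Gaussian entry
noise and Gaussian angular noise about a random perpendicular axis; the
mean 3-D entry displacement at `sd = 1` mm follows the Maxwell mean
`sqrt(8/pi) ≈ 1.60` mm, which the tests verify.

## Numerical choices

* A point belongs to the voxel whose center is nearest; label lookups are
  nearest-neighbor. Ray casting steps at half the minimum spacing so a
  one-voxel cortex cannot be skipped.
* Pedicle width is the minimum caliper diameter over cross-sections along
  the corridor's middle 80% (stations every 0.5 mm, 1° direction grid),
  with the caliper over voxel centers compensated by one voxel cube's
  support along the probe direction. The narrowest dimension — not an
  area-equivalent diameter — is what bounds the screw.
* Wall clearances march from a fan of offset columns spanning the screw's
  width (0.1 mm march step), so corners of the cylinder facing a curved
  wall are captured; the test suite holds the result to within 0.2 mm of a
  10^4-point surface-sampling oracle.
* The exact statistics are implemented from their formulas (log-factorial
  hypergeometric enumeration with probability ordering for Fisher; the
  textbook paired-t statistic). `stats::fisher.test`, `stats::t.test`,
  exhaustive enumeration and sign-permutation Monte-Carlo serve as
  independent oracles in the tests, never as the implementation.
* Degenerate inputs raise typed conditions (`pedplan_missing_structure`,
  `pedplan_planning_infeasible`, `pedplan_degenerate_test`, ...) rather than
  generic errors, and reporting functions report rather than throw.

## Problem sizes and test design

The default phantom grid is roughly 80 × 84 × 54 voxels (~360k), generated
in ~0.3 s. The planner's default search grid evaluates a few thousand
candidates per side (~1 min); the test suite and the acceptance script use
a coarser but still exhaustive grid (±9° × ±6°, 3° steps, 2 mm entry grid,
a few hundred candidates, seconds per side) — the same rules at a coarser
resolution, chosen so a full phantom sweep stays interactive. The planner
safety sweep uses 20 phantoms with widths 7–13 mm; measurement recovery
uses 20 phantoms with widths 6–14 mm; grading is validated on 50 randomized
poses against a 10×-denser brute-force oracle.

## Known limitations

* The pullout-force proxy is ordinal, not biomechanically calibrated.
* Phantoms are axis-aligned, single-vertebra, and noise-free in geometry;
  scoliotic anatomy, multi-segment coordination and rod planning are out of
  scope.
* Grading assumes a clean label map; real postoperative CT with metal
  artifacts is not handled.
* The entry-funnel exclusion means a breach within one screw diameter of
  the entry site is attributed to the entry, not graded as a wall breach.
* The planner's "longest first" hierarchy can prefer a longer, thinner
  screw over a shorter, thicker one when the pullout proxy says so; no
  bilateral symmetry is enforced.
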