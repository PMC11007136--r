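---
title: "Volumetric resection-margin mapping with digital specimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric resection-margin mapping with digital specimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specimargin)
```

## The problem

After resection of a tongue carcinoma, the pathologist reports for five
anatomical locations — anterior, posterior, craniomedial, caudolateral and
deep central — whether the resection margin (the shortest tumor-to-surface
distance) is *adequate* (≥ 5 mm) or *inadequate* (< 5 mm). Conventional
assessment works on cross-sectional tissue blocks of roughly 3–5 mm cut
perpendicular to the anterior–posterior axis, so it samples the specimen
sparsely and quantizes the anterior/posterior margins to whole blocks.
A *digital specimen* instead represents the whole specimen volumetrically:
the outer contour as a closed surface, the tumor as a voxel support, and the
margin as a distance map over the surface. `specimargin` implements this
pipeline — surface extraction, five-region partition, margin mapping,
reconstruction of a volume from registered serial sections, and
agreement/diagnostic-accuracy statistics — and ships a phantom generator
with brute-force ground truth so every stage can be validated end to end.

## Coordinate and data model

All geometry is in world millimetres. A `labeled_volume` holds one integer
grid with labels background (0), specimen (1), tumor (2), mucosa (3); the
*specimen support* is the union of labels 1–3, and mucosa voxels must lie on
its boundary. Voxel `(i, j, k)` (1-based) has its center at
`origin + (c(i, j, k) - 1) * spacing`; every distance in the package is
computed center-to-center on this convention, which keeps each operation
testable against exhaustive oracles. The y axis is the anterior–posterior
axis (+y anterior), +z points toward the mucosal (superficial) side, and
histological sections are xz-planes stacked along y.

## Surface extraction

No marching-cubes implementation is available in this R environment, so
`extract_surface()` uses dual contouring ("naive surface nets") on the
binary indicator at iso-level 0.5: one vertex per boundary cell, placed at
the mean of the cell's edge-crossing midpoints, and one quad (two triangles)
across every inside/outside voxel face. The mesh is closed, watertight and
consistently oriented by construction. On a digitized ball of radius 10 mm
at 0.5 mm voxels the surface area is about +3% and the enclosed volume
about −0.1% versus the analytic sphere, inside the 5% band the validation
suite enforces. Optional `smoothing` applies two rounds of neighborhood
averaging; it is off by default so the analytic oracles stay tight.

## Distance fields and margin maps

`euclidean_distance_field()` stores, for each voxel, the exact Euclidean
distance (anisotropic spacing respected) from its center to the nearest
voxel center of the target label, computed with a kd-tree; tests verify
exact equality with all-pairs enumeration on small grids. The margin map
interpolates this field trilinearly at every outer-surface vertex. Mucosa
vertices are excluded by default (a mucosal surface is anatomy, not a
resection plane); the flag `exclude_mucosa = FALSE` re-includes them for
sensitivity analyses. Per region, the reported margin is the **minimum**
over assessed vertices — matching minimal-margin reporting — and the call
is *inadequate* iff that minimum is strictly below the 5 mm threshold. A
region whose vertices are all excluded is reported `not_assessable`, never
silently adequate.

Measuring distances to the tumor *voxel support* (not a meshed tumor
surface) is deliberate: it keeps brute-force oracles exact. It carries a
known inward bias of roughly a third of the voxel size, because dual-contour
vertices sit slightly inside the nominal iso-surface. At the default 0.3 mm
spacing this is ~0.1 mm. One consequence is worth knowing: a phantom built
with an exact 5.0 mm margin measures just *below* 5.0 mm and is therefore
called inadequate by the strict rule. The validation suite asserts the
band (±1 voxel diagonal) and documents this boundary behavior rather than
hiding it.

## The five-region partition

The deep central region is the part of the surface inside a cone whose apex
sits at the tumor centroid (an explicit `apex_override` mirrors manual
placement) and whose axis is the deep-oriented normal of a total-least-squares
plane through the mucosa vertices. The half-angle defaults to 45°: the
conventional 2D rule draws two 45-degree lines from the tumor center
relative to a mucosa-parallel line, making the deep wedge subtend 90°, and
we adopt that reading for the 3D cone (the alternative — a 45° *apex* angle,
i.e. 22.5° half-angle — is available via `half_angle_deg`). Points exactly
on the cone boundary tie-break into the deep region.

The rest of the surface is divided into quadrants by azimuth about the cone
axis, measured from the anterior direction (the projection of
posterior→anterior onto the cone-base plane): `[-45°, 45°)` anterior,
`[135°, 225°)` posterior, and the two remaining quadrants craniomedial /
caudolateral, disambiguated by a user-supplied hint vector. Azimuth sectors
centered on the anterior/posterior directions are the only reading that
produces quadrants actually named anterior/posterior/craniomedial/
caudolateral; half-open intervals make boundary assignment deterministic.
A geometric consequence of the 45° cone: the lateral-region minimum margin
occurs at the cone boundary and cannot exceed ~√2 times the deep margin for
a convex specimen, so "deep inadequate with laterals ≫ threshold" scenarios
only exist when the deep margin is itself close to the threshold.

## Conventional slice-based emulation

`conventional_slice_margins()` transcribes the pathologist's protocol:
anterior/posterior margins are (count of tumor-free blocks at that end) ×
(specimen length / block count) — a step function with the block thickness
as quantum — and, on each tumor-bearing section, the deep wedge between the
two 45° lines and the two lateral sectors yield 2D minimum tumor-to-contour
distances, aggregated across sections by minimum (consistent with
minimal-margin reporting; the aggregation rule is exposed to scrutiny here
because the convention leaves it implicit). The mucosa-parallel line per
section is the principal direction of that section's mucosa pixels, with a
horizontal fallback when a section carries no mucosa.

## Section registration and stacking

Sections are registered by paired landmarks with a closed-form
least-squares similarity transform (rotation, isotropic scale, translation;
SVD of the cross-covariance with the determinant constraint, so reflections
are excluded). Similarity rather than affine matches what mounting a
section physically does — rotation and translation — while the scale degree
of freedom partially compensates tissue shrinkage. Stacking resamples each
section through its transform (nearest neighbor — labels are categorical)
and replicates each section across its slab (nearest-section fill): a 4 µm
stained section stands in for its whole 3–5 mm block, exactly as a
pathologist extrapolates. Inter-section spacings are inputs; the simulator
records the true values.

## Agreement and diagnostic accuracy

Two tumor outlines are compared through their Boolean intersection I:
underestimation is the 95th-percentile Hausdorff distance (95HD) between
the reference surface and the surface of I, overestimation the 95HD between
the test surface and the surface of I. The 95HD is the max of the two
directed 95th-percentile nearest-distances ("surfaces" are boundary
voxel-face center point sets, which keeps small-scale oracles exact); the
max-of-directed form is the informative choice because the intersection is
a subset of each operand, making one direction trivially near zero. An
empty intersection yields flagged not-defined distances instead of
infinities, so disjoint outlines are distinguishable from huge errors.
Percentile and symmetry mode are parameters.

Region-level calls (inadequate = positive) are summarized as sensitivity,
specificity, PPV and NPV with exact Clopper–Pearson 95% intervals
(`stats::binom.test`; the closed-form beta-quantile is the independent
oracle in tests). The exact method is the only standard interval consistent
with published bounds like "94% (71%–100%)" for 16/17 — Wilson's upper
bound there is 99%. Ratios with zero denominators are reported not-defined.
`reconstruct_confusion_matrices()` inverts rounded integer-percent metric
quadruples back to the (often unique) integer confusion matrix by
exhaustive enumeration, which is how the validation suite re-derives counts
from published accuracy tables.

## What the phantom generator emulates — and what it does not

`generate_phantom()` builds smoothed ellipsoids (optional smooth radial
bump noise) rather than anatomical tongue meshes: the margin rules depend
only on orientation, and ellipsoids keep analytic oracles available.
Defaults mirror the emulated study conditions:

* specimen semi-axes (18, 25, 14) mm — fits the 59 mm-diameter imaging
  container bore with room to spare;
* isotropic 0.3 mm voxels, the high-resolution 3D imaging scale;
* tumor semi-axes (6, 7, 5) mm under a mucosal cap, at clinical
  depth-of-invasion scale (the cohort being emulated spans ~1–16 mm);
* mucosa = boundary voxels whose outward normal is within 60° of +z;
* ground truth: dense boundary-face sampling of the resection surface,
  classified by a region classifier written independently of the pipeline's
  partition code, with exact nearest-tumor distances.

`perturb_tumor_outline()` models an observer as a smoothly varying signed
offset of the tumor surface: a Gaussian-filtered noise field (default 4 mm
correlation length) is subtracted from the signed distance and thresholded
at the bias. Positive bias dilates — the dominant radiologist behavior this
package quantifies — and the study defaults (+1.5 and +0.8 mm bias, 0.6 mm
roughness for the two simulated observers) produce overestimation far
exceeding underestimation, reproducing the qualitative headline that NPV
exceeds PPV for inadequate-margin detection.

`simulate_sectioning()` cuts coronal sections at jittered thicknesses
(nominal 4 mm, rescaled so `ceil(length/thickness)` sections span the
specimen), shrinks healthy tissue radially about the tumor (default 0.95;
the tumor keeps its size, the transition is blended), optionally tears a
peripheral wedge from one section, applies a random in-plane mounting
transform per section, and carries true contour landmarks through every
map. Shrinkage magnitude and container compression are not quantified in
the emulated protocol; 0.95 and "off" are placeholders exposed in the
configuration.

Not modeled: image intensities and acquisition physics, fixation
biomechanics beyond the radial scale/rupture model, anatomical landmark
detection, deformable registration, and real observer behavior beyond a
biased smooth offset. Passing tests therefore demonstrate the geometry,
statistics and plumbing are right — not that real radiologists or real
tissue behave like the simulator.

## Numerical choices and degenerate inputs

* Iso-level 0.5 on the binary indicator; no smoothing by default.
* Distances center-to-center; one voxel diagonal is the natural tolerance
  quoted throughout the tests.
* Cone boundary ties go deep; azimuth intervals are half-open on the lower
  side; percentile quantiles use R's default (type 7) definition.
* Degenerate inputs raise classed errors (`specimargin_error_*`): unknown
  labels, non-positive spacing, empty supports, interior mucosa, < 3
  mucosa vertices or collinear mucosa, coincident landmarks, reflections,
  annihilating erosions, overlapping slabs, zero-denominator ratios.
* NIfTI headers store geometry as 32-bit floats; round-trips are bit-exact
  only for values representable in single precision (0.125, 0.25, 1.0, …),
  and 0.3 mm becomes 0.30000001 on disk.

## Problem sizes used by the validation suite

The package defaults target the emulated study (0.3 mm voxels). The test
and acceptance runs use coarser grids chosen as a package design decision
to keep the full suite fast while leaving every tolerance expressed in
voxel units: oracle-equivalence checks run on ≤ 25³ grids; phantom-level
checks at 0.5–1.5 mm spacing; cohort-level properties (9 phantoms × 5
regions = 45 region slots per run; 20 seeded cohorts for the NPV ≥ PPV
property) at 1.2 mm spacing. `run_study()` at the 0.3 mm default is the
same code path and simply takes proportionally longer.

## Known limitations

* The inward discretization bias of the margin map (above) makes
  exact-threshold phantoms resolve to inadequate; thresholds should be
  interpreted with the voxel-diagonal tolerance in mind.
* The quadrant construction from "two perpendicular planes" is
  underdetermined in the conventional protocol; the azimuth-sector reading
  implemented here is a documented design choice.
* Landmark correspondence is by list order and assumed given; there is no
  automatic landmark detection.
* The HE-like reconstruction inherits the outer contour from the imaging
  volume (as in the emulated workflow), so outer-contour segmentation error
  is out of scope.
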