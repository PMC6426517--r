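---
title: "Automatic four-field box planning: models, parameters and design choices"
author: "fourfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic four-field box planning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which knobs
matter, and where the design was genuinely open. The pipeline plans
four-field box pelvic radiotherapy fully automatically: CT in, reviewable
plan out. Everything below is organized along the pipeline.

## Coordinate conventions

One fixed convention is used everywhere, because aperture-side mirror bugs
are the characteristic failure of BEV code: world axes are patient-left,
patient-posterior and patient-superior positive, in mm; voxel indices are
0-based in the world mapping (`world = origin + index * spacing`) with the
origin at the *center* of the first voxel; gantry angles follow IEC for a
head-first supine patient (0 = source anterior, 90 = source at the patient's
left). BEV axes are `v` = patient superior and `u = axis × v`, so patient-left
is +u in the AP view and opposed beams see mirrored u — the mirror-consistency
of AP/PA and LL/RL apertures is asserted by tests.

## Couch removal and body contour

The couch detector reduces the volume to a per-row (anteroposterior) count of
voxels above `couch_hu_threshold` (default −500 HU) and walks the runs of
occupied rows from the posterior edge anteriorly. A run qualifies as couch if
it is slab-like: at most 30 mm thick and at least half as wide as the widest
occupied row in the volume. The gate exists because the first strong
"peak" from the posterior is otherwise the posterior body wall; thickness
and width separate the two robustly. A volume without a couch simply reports
`found = FALSE` — absence is not an error. Removal blanks everything
posterior to the detected top row to −1000 HU, which assumes a flat,
z-invariant couch top (curved or indexed couches are out of scope).

Body contouring thresholds at `body_hu_threshold` (default −300 HU, the
conventional CT externals value), keeps the largest 26-connected component,
fills internal cavities, and applies a closing-then-opening with a 3 mm ball.
Cavity filling is 3D by default; slice-wise 2D and the 2D+3D combination are
available (`hole_fill`), 3D being the default because it also closes cavities
that tunnel obliquely through slices while leaving genuinely open channels
(e.g. bowel gas communicating with the exterior) untouched. After smoothing,
the mask is reduced again to its largest component and re-filled, so the
output is a single hole-free component by construction, not by hope.

## Marked isocenter

Fiducial search is restricted to a shell of ±10 mm (`bandwidth_mm`) around
the body surface, computed by seeded dilation from the boundary voxels; this
keeps dense bone and bowel contrast out of the candidate set by geometry
rather than intensity. Candidates are 26-connected components above
`fiducial_hu_threshold` (800 HU) with 1–200 voxels; each contributes an
intensity-weighted centroid. Roles are assigned by position (most anterior =
anterior mark, remaining two = laterals by side) and the winning triple
minimizes an explicit inconsistency score: lateral disagreement in y, spread
in z, and lateral off-centering of the anterior mark. The selection is an
exhaustive enumeration over triples, so a test can verify it against an
independent re-implementation exactly; ties break deterministically by total
voxel count, then residual.

The intersection rule is the one skin marks actually constrain: x from the
anterior mark, y from the mean of the laterals, z from the mean of all three.
The residual (maximum per-axis spread) is carried into the report because the
known failure mode — fiducials placed on adjacent axial slices — should be
visible to the reviewer, not averaged away silently.

## The synthetic phantom

Real planning CTs with fiducials and couch are not publicly available, so the
package generates them: an elliptical soft-tissue body (170 × 105 mm
half-axes) on a couch slab with an air gap, a bony pelvis built from an
annulus whose inner opening *is* the pelvic inlet (130 mm default), an
inferior obturator frame with two circular openings, a pubic symphysis block,
a sacrum slab, two femoral heads and L4/L5 vertebral cylinders with an 8 mm
interspace, three skin fiducials whose axis lines intersect exactly at the
intended isocenter, optional 300 HU bowel-contrast blobs, and independent
Gaussian HU noise (σ = 15 by default). The grid is 248 × 184 × 80 voxels at
1.5 × 1.5 × 3 mm — planning-CT-like in-plane resolution with a realistic
slice thickness.

Fiducials are rasterized with partial-volume mixing (supersampled overlap
fractions), which is what makes their size a real physical constraint: a 2 mm
sphere (4.2 mm³) split across voxels of ≥ 2.5 mm³ can never lift any single
voxel past a few hundred HU, so it is undetectable by any honest intensity
threshold at clinical grids. Clinical practice uses 3–4 mm radiopaque markers
for exactly this reason, and the phantom default is a 4 mm, 2000 HU sphere.

What the phantom deliberately does not emulate: CT texture and reconstruction
artifacts, metal streaks, curved couch tops, arms-in-field anatomy, or
realistic bone shapes. The planning rules consume projected silhouettes and
landmark geometry, which the schematic shapes provide with exact truth — so
passing tests demonstrate that the *chain* recovers known geometry under
noise, not that the segmenters would survive arbitrary clinical CTs. The
surrogate bone segmenter in particular (threshold + geometric labeling) is a
stand-in interface for a real multi-atlas segmentation, which is out of
scope.

Cohorts jitter body size (±12/±8 mm), inlet width (±12 mm), isocenter
(±10/±8/±9 mm) and couch height (±6 mm) uniformly, with per-item seeds
derived from the cohort seed; generation is bit-reproducible.

## BEV projection and landmarks

Projection is divergent (point source, SAD 1000 mm): each mask voxel's center
is projected through similar triangles onto the isocenter plane, and the
voxel contributes its magnified axis-aligned footprint to the BEV raster.
Splatting the footprint rather than the center point matters because the
slice spacing (3 mm) exceeds the BEV pixel (1.5 mm): center-point projection
leaves empty raster rows through which the pelvic inlet "leaks" into the
background and stops being an enclosed opening.

Landmarks come from the silhouettes: the inlet is the enclosed background
opening of the AP bony-pelvis projection with the widest u extent; its
extreme pixel centers give the inlet borders, and the inferior extent of the
remaining enclosed openings gives the obturator landmark. The L4/L5
interspace is the midpoint between the inferior extent of L4 and the superior
extent of L5; if L4 could not be labeled (fused column), the top of L5 is
used and the superior border is flagged for review — mis-segmented vertebrae
are the dominant cause of wrongly placed superior borders, so this failure
mode degrades loudly rather than silently. Lateral-view landmarks
(symphysis anterior, sacrum posterior) are stored in the right-lateral view,
where anterior is +u, so margin arithmetic keeps its signs.

## Aperture rules and MLC

The field borders are affine in the landmarks, with every margin a
configuration key (`rule_config()`): laterally 20 mm beyond the inlet on each
side (the conventional "2 cm wider than the pelvic inlet", read as per-side),
superior margin 0 above the interspace, inferior margin 0 below the obturator
openings, 10 mm in front of the symphysis and 5 mm behind the sacrum. The
margins are configuration because aperture rules legitimately vary with
disease extent. MLC leaves are 10 mm wide, edges aligned to multiples of the
leaf width around v = 0, collimator fixed at 0; each leaf pair opens to the
polygon's exact u extent within its band (vertices plus band-plane
intersections), so the fitted opening covers the polygon and over-covers by
at most one leaf width in v.

## Dose model and weight optimization

The dose engine is a deliberate stand-in for a commercial TPS calculation:
primary attenuation only, `B(d) · exp(−μ_eff · max(0, d − d_b)) · (SAD/r)²`
with a linear buildup ramp `B`, water-equivalent body (unit density inside
the contour, zero outside), binary field edges, no scatter and no penumbra.
Defaults `μ_eff = 0.02 cm⁻¹`, `d_b = 3.2 cm` for the 18 MV label. The
optimization and metrics layers need only linearity in the weights and
realistic geometric asymmetry, which this provides; absolute dosimetric
accuracy is a non-goal. Radiological depth is a ray integral sampled at half
the smallest voxel (midpoint rule, nearest-neighbor mask lookup).

Weights minimize `Σ_{v∈treated} (Σ_b w_b d_b(v) − R)²` subject to `w ≥ 0`;
negative beam weights are physically meaningless, so the least-squares
problem is solved as NNLS — by exact active-set enumeration (16 subsets for
4 beams, KKT-checked), which is deterministic and needs no iterative solver.
The treated volume is the voxelwise intersection of body and all four MLC
openings, eroded by 5 mm. After optimization the weights are rescaled so the
isocenter voxel receives exactly the prescription (clinical normalization;
treated-volume-mean normalization is available). The optimality property
tested ("optimized objective ≤ equal-weights objective") compares raw NNLS
optima against the equal-weight vector, which is the mathematically
guaranteed comparison; the renormalized weights are what enter the reported
plan. The equal-weight reference plan gives each beam R/4 at the isocenter.

The hottest-1-cc metric sorts dose over the whole body ("tissue", not just
the treated volume; restrictable by argument), takes the voxel set whose
cumulative volume first reaches 1 cc and reports its minimum dose as % of
prescription; V95 counts treated voxels at ≥ 95 % of prescription by voxel
center. Plans with D1cc ≥ 107 % are flagged hot.

## Numerical choices and degenerate inputs

* Surface distances (Dice / mean surface distance / Hausdorff) are between
  boundary-voxel centers (face-adjacency boundary, grid border = background),
  symmetrized as mean-of-directed-means and max-of-directed-maxima; the
  Hausdorff is the strict 100th percentile by default with a percentile
  option. Sub-voxel surface meshing was rejected: it changes no test
  semantics and breaks exhaustive oracle checking.
* The shell, erosions and dilations use boundary-seeded dilation with exact
  Euclidean-ball offset sets, so morphology cost scales with surface, not
  volume.
* Stage failures (no fiducials, empty threshold mask, missing bone
  structure, empty beam intersection) abort with a classed condition naming
  the stage; the CLI maps stages to distinct exit codes and writes a report
  stub.
* Determinism: the phantom isolates and restores the RNG state; the pipeline
  itself has no randomness; reports are byte-identical across reruns modulo
  the timing block, which can be excluded.

## Problem sizes

The validation cohorts are sized for a single CPU: 20 phantoms (σ = 15 HU)
for body-contour and isocenter recovery, 10 full plans on an off-center
cohort for the optimization comparison, and small constructed grids for the
oracle equivalences (all-pairs surface distances, per-voxel projection,
voxelwise treated-volume membership, dense grid-search NNLS). The acceptance
script regenerates all of it from a single seed.

## Known limitations

Schematic anatomy only; threshold-based surrogate bone labeling; flat couch;
no penumbra or scatter in dose; no organ-at-risk constraints, wedges or
field-in-field; no DICOM-RT export (NIfTI and JSON are the interchange
formats); physician-style plan acceptability cannot be simulated and is not
claimed.
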