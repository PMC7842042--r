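---
title: "Cartilage compensation for CT bone models: method, phantom and validation design"
author: "ChondroCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cartilage compensation for CT bone models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The reconstruction problem

A plain CT of the elbow shows bone at high attenuation and everything else
— cartilage, synovial fluid, capsule — at low, poorly separated
attenuation. Segmenting bone with the standard 250–2500 HU window
therefore yields the *subchondral* surface of the radial head: the true
articular surface sits one cartilage thickness (0–3.5 mm on the radial
head) outside it. A prosthesis milled from such a model is systematically
undersized on every articular dimension.

The compensation implemented here rests on one geometric observation: in
an intact, apposed joint the two subchondral surfaces are separated by the
two cartilage layers (plus any film of fluid). The bone-only image
therefore *does* encode the total cartilage thickness across each joint —
as the width of the radiolucent joint space — even though it cannot
attribute it to either side. The method splits that space evenly:
each articular subchondral boundary is translated **half** the measured
subchondral gap toward the opposing bone.

## The procedure

### Proximal radioulnar joint (per axial slice)

1. **Reference circle.** The nonarticular portion of the radial-head
   cross-section is modelled as a circular curve and fitted by linear
   least squares on the algebraic circle equation. The fit is iterated:
   a first round excludes the half-plane facing the ulna (a guess at the
   articular sector), junctions are detected, and a second round refits
   with the detected articular arc (plus a 2% index margin) excluded.
2. **ANA junctions.** Walking the contour from the most ulna-averted
   point in both directions, a junction is the first point whose *inward*
   radial deviation from the reference circle exceeds `deviation_tol`
   and stays exceeded over a 5° persistence arc. Inward-only detection is
   deliberate: subchondral bone is recessed *under* its cartilage, so a
   genuine alteration is always a recession, while circle-vs-ellipse
   misfit on a quasi-elliptic section can point either way.
3. **Smooth-conic null test.** Before any circle fitting, a global conic
   is fitted to the whole contour. If its RMS Sampson distance is below
   `deviation_tol / 4` the contour is a single smooth (quasi-elliptic)
   curve and "no articular alteration" is reported. Without this test,
   the exclusion-based circle fit extrapolates across the flatter side of
   a healthy elliptic section and can manufacture a recession of almost a
   millimetre. The threshold separates voxelisation ripple (about
   0.04 mm RMS at 0.2 mm voxels) from the misfit left by a genuine
   0.5 mm recession (about 0.12 mm).
4. **Reforming axis and gap.** The axis is the perpendicular through the
   midpoint of the junction chord, oriented toward the ulna; it
   operationalises the "mid portion of the radial notch", for which no
   coordinates exist. The gap is the distance from the last crossing of
   the head contour to the first crossing of the ulnar contour along that
   ray, measured between sub-voxel iso-surface boundaries — halving a
   gap quantised to whole voxels would double the quantisation error.
5. **Reform.** The articular sub-arc is rigidly translated by `gap / 2`
   along the axis and re-joined to the junctions by blending arcs tangent
   to the reference circle (straight closures if an arc would
   self-intersect). Only the *added* area is rasterised back into the
   mask, so interior structure (the dish cavity in near-crest slices)
   is preserved and the compensation never removes volume.

Slices where both bones appear but no alteration is detectable pass
through unchanged — that is the correct behaviour for a cartilage-free
joint, not an error. Slices whose measured gap exceeds a plausibility
bound (`max_gap`, default 8 mm: more than two maximal cartilage layers
plus fluid) or whose reform cannot produce a simple polygon are skipped;
these arise from degenerate ring-shaped sections within half a cartilage
thickness of the rim crest.

### Radiocapitellar joint (one rigid 3-D translation)

The articular patch is the upward-facing head surface that sees the
capitellum along the axial direction, restricted to the proximal surface
band (`dish_window`, default 6 mm below the most proximal head point —
without this restriction a shaft or tuberosity voxel column under the
capitellar footprint could masquerade as the dish). The gap is measured
by the ray from the dish's deepest subchondral point, and the patch is
translated by half of it — a single rigid translation, matching the
one-arrow depiction of the manoeuvre, not per-slice deltas. A linear
taper blends the patch border where it abuts un-raised head surface.
The translation direction must be the grid's axial axis; oblique
directions are rejected. Order matters and is fixed: radioulnar first,
then radiocapitellar on the updated solid, because the rim translation
changes the dish border the second stage blends into.

### Exactness

Two identities are exact by construction, not approximation targets:
the applied translation equals the measured gap divided by two to machine
precision in every slice, and for equal cartilage thickness `t` on both
sides of a joint with no fluid the reformed border lands on the true
cartilage surface at the measurement ray (with fluid `f` it overshoots by
exactly `f / 2` — the method's known bias). Away from the measurement
ray the rigid translation accrues an error that grows with angular
distance from the mid-articular direction, roughly `t (1 - cos φ)`; this
is inherent to translating a curved arc rigidly and is the main residual
in the compensated model.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `hu_low`, `hu_high` | 250, 2500 | HU | standard bone segmentation window, closed range |
| `deviation_tol` | `max(0.3, 1.5 × in-plane voxel)` | mm | above voxel ripple, below one of the thinnest cartilage layers |
| `persistence_deg` | 5 | deg | suppresses single-point noise junctions |
| `max_gap` | 8 | mm | two maximal cartilage layers plus fluid |
| `dish_window` | 6 | mm | deeper surface cannot be articular dish |
| ICP `max_iter`, `tol_mm`, `subsample` | 100, 1e-5, 6000 | — | see registration notes |
| `alpha` | 0.01 | — | the study's significance level |

## The synthetic phantom

No cadaver scans are distributable, so validation uses a synthetic elbow
whose ground truth is analytic. The phantom emulates:

* a radial head with elliptic subchondral section (coronal semi-axis
  drawn 9.4–10.4 mm, sagittal 0.1–0.5 mm larger), a spherical articular
  dish (depth 2 mm) and a neck/shaft with a radial tuberosity bump;
* cartilage as an outer envelope: the rim wall sector facing the ulna
  (azimuth −55° to 115°) is recessed by the rim cartilage thickness, the
  dish and rim crest carry cartilage on the full circumference — so the
  bone contour shows exactly the "alteration of the circular curve" the
  detection looks for;
* an ulnar radial notch (concave wedge apposed to the rim) and a
  capitellar sphere, each with its own cartilage layer; apposed layers
  share a thickness (notch = rim, capitellum = dish), the regime in which
  halving the gap is exact;
* dish cartilage thinner than rim cartilage (cohort ratio U(0.35, 0.6)).
  This is the anatomy that makes plain CT underestimate the disc depth:
  the gold depth is `dishDepth + rimCartilageT − dishCartilageT`, the
  bone-only depth just `dishDepth`. With equal thicknesses the two cancel
  and all three models agree on depth;
* voxels of 0.2 × 0.2 × 0.3 mm (the scan resolution throughout), bone at
  700 HU, cartilage 80 HU, soft tissue 30 HU, additive Gaussian noise of
  10 HU — values chosen to straddle the 250 HU threshold the way real
  tissue does.

The gold-standard surface is an exact parametric triangulation of the
envelope solid (a voxel-sampled truth surface was found to bias
nearest-point RMS low by ~0.06 mm, because its ripple offers closer
points). The bone-only truth mesh is voxel-sampled, since its recessed
sector has azimuthal steps that a structured parametrisation handles
poorly and the voxel grid handles naturally.

What the phantom does **not** emulate: cartilage covering 240–360° of the
rim (the junction detection cannot bound an arc wider than 180°, so the
emulated sector is the widest the method supports that still covers the
sagittal measurement azimuth); partial-volume blur, beam hardening and
metal artefacts; anatomical asymmetry of the medial and lateral rims;
cartilage thickness varying along a single surface. Passing tests on the
phantom therefore demonstrate the geometric correctness of the pipeline
under the method's own assumptions, not robustness to every property of
clinical scans.

## Morphometry and registration choices

* **Diameters are chords**, measured along the lines through the
  disc-centre axis (coronal: the disc-centre-to-tuberosity direction;
  sagittal: perpendicular), at the axial level with the longest coronal
  diameter on the gold model — not bounding-box extents. A bounding-box
  reading would let the nonarticular sliver of the rim mask the cartilage
  deficit in the sagittal direction.
* **Rim thickness** is the distance parallel to the axial normal from the
  head-neck junction line to the most proximal point of each rim in the
  coronal section; medial is the ulna-facing side. The junction line
  connects the two profile-curve vertices (the point of each coronal
  profile farthest from its endpoint chord). The profile runs from the
  neck's narrowest level — the first local radius minimum walking
  distally from the widest level, so the tuberosity cannot capture it —
  up to the rim.
* **Disc depth** takes the *upper envelope* of the coronal section
  between the rims as the articular surface (per 0.3 mm bin the most
  proximal point), so the head's distal under-face and the shaft outline,
  which also lie between the rims, cannot pose as the dish.
* **Disc centre** is the surface point farthest below the best-fit rim
  plane, restricted radially inside the rim loop and to half a rim radius
  below the plane; exact ties (flat-topped solids) resolve to the
  centroid of the tied set.
* **Registration** is point-to-point ICP on the tuberosity–diaphyseal
  region with deterministic initialisation (identity or centroid +
  principal axes, whichever starts lower). Two refinements address the
  near-cylindrical symmetry of that region: a linearised point-to-plane
  step is tried each iteration but accepted only if the point RMS does
  not increase (preserving the monotone-RMS property), and at apparent
  convergence each principal-axis rotation mode is polished by direct 1-D
  minimisation of the region RMS — rotation about the shaft axis is the
  mode plain ICP leaves under-determined. RMS deviation uses
  nearest-point-on-surface (point-to-triangle) correspondences, reported
  asymmetrically with the model under test as source and the gold
  standard as target.

## Statistics

Model types are compared within specimens: the tie-corrected Friedman
rank statistic with `k − 1` degrees of freedom, followed (as the
multiple-comparison companion) by Dunn-type z-tests on the within-subject
mean ranks, two-sided, Bonferroni-multiplied by the number of pairs and
capped at 1. Significance is assessed at 0.01.

One behaviour of the phantom deserves flagging: because the dish patch is
raised rigidly, the compensated model's disc depth equals the bone-only
model's depth in every specimen, so the gold-vs-compensated pairwise
comparison for depth sits near the 0.01 boundary (adjusted p ≈ 0.01–0.04
depending on seed) — the compensation recovers the dish *surface* exactly
but cannot recover a depth deficit caused by rim cartilage exceeding dish
cartilage. The overall Friedman test still separates the three model
types on depth, driven by the bone-only deficit.

## Problem sizes and numerical notes

The validation suite runs one full-resolution phantom (about 2.8 million
voxels, meshes of 100k–250k vertices) for the surface-recovery check and
an eight-specimen cohort at the same resolution for the statistics;
property and oracle tests use analytic contours, small voxelised solids
(spheres at 0.2–0.8 mm) and random 8 × 3 matrices. Degenerate inputs are
errors with named messages (empty masks, collinear circle fits, straight
profiles, oblique DICOM series); ties break deterministically (first
along the curve for profile vertices, centroid for depth ties, the
head-adjacent level for neck-waist ties). STL topology is rebuilt by
exact coordinate matching; marching tetrahedra use a fixed six-tetrahedron
cell split whose face diagonals agree between neighbouring cells, which
is what makes every extracted surface watertight without repair.
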