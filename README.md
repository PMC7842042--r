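# ChondroCT

Cartilage-compensated reconstruction of proximal-radius models from CT.

## The problem

Patient-specific radial head prostheses are designed from 3-D digital models
of the proximal radius. Plain CT segments only *subchondral bone*: the
articular cartilage layer (anywhere from 0 to 3.5 mm thick on the radial
head) is invisible, so a CT-derived model underestimates the head diameters,
the rim thickness and the articular disc depth — exactly the surfaces a
prosthesis must replicate. CT arthrography (CTA) shows the cartilage but
requires an intra-articular contrast injection.

ChondroCT implements a cartilage-reproducing image reconstruction method
that recovers the cartilage-bearing surface from plain CT alone, using the
one place where the cartilage geometry *is* encoded in a bone-only image:
the gap between apposed subchondral surfaces across a joint.

## The method

In every axial slice through the proximal radioulnar joint:

1. The nonarticular portion of the radial-head cross-section is modelled as
   a circular curve; the **articular–nonarticular (ANA) junctions** are the
   points where the contour departs from that circle (the subchondral bone
   of the cartilage-covered sector is recessed below the smooth outer
   envelope).
2. A **reforming axis** is erected perpendicular to the chord between the
   two junctions, through its midpoint.
3. The subchondral **gap** `g` between the radial head and the ulnar radial
   notch is measured along that axis, and the articular portion of the
   contour is translated by `g / 2` toward the ulna — each bone's cartilage
   is assumed to occupy half the joint space.
4. The uneven borders over the junctions are filled with blending arcs so
   the reformed boundary runs on the same arch.

At the radiocapitellar joint the articular dish is translated proximally,
as one rigid patch, by half the dish-to-capitellum subchondral distance.
For apposed cartilage layers of equal thickness `t` and no free fluid, the
reformed border lands exactly on the true cartilage surface: `g = 2t` and
the translation is `t`.

Around this core the package provides Hounsfield-threshold bone
segmentation (250–2500 HU), seeded 26-connectivity bone labelling,
watertight marching-tetrahedra isosurfaces, STL/PLY/NIfTI/DICOM I/O, rigid
ICP registration on the tuberosity–diaphyseal region, nearest-point-pair
RMS deviation maps, the five standard radial-head parameters (coronal and
sagittal diameter, medial and lateral rim thickness, disc depth) measured
in a reference frame fixed on the gold-standard model, Friedman rank tests
with Bonferroni-adjusted pairwise comparisons, and a synthetic elbow
phantom generator whose analytic bone+cartilage geometry stands in for
cadaver CTA as the ground truth.

## Worked example

```r
library(ChondroCT)

spec  <- phantomSpec()          # 0.2 x 0.2 x 0.3 mm voxels, 1 mm cartilage
vol   <- rasterizePhantom(spec) # synthetic elbow CT volume
truth <- buildTruth(spec)       # analytic gold standard + landmarks

cir <- runCIRM(vol, truth$truth_landmarks$seed_points)

head_region <- RegionSpec(plane = list(
  point  = c(0, 0, truth$truth_landmarks$junction_height),
  normal = c(0, 0, -1)))
rmsDeviation(cir$ct_mesh,   truth$cartilage_mesh, region = head_region)$rms
#> [1] 0.7260781
rmsDeviation(cir$cirm_mesh, truth$cartilage_mesh, region = head_region)$rms
#> [1] 0.2645699

frame <- referenceFrame(truth$cartilage_mesh,
                        truth$truth_landmarks$tuberosity_point)
as.data.frame(measureAll(cir$cirm_mesh, frame))
#>   coronal_diameter_mm sagittal_diameter_mm medial_thickness_mm
#> 1                21.6                 21.8               10.25
#>   lateral_thickness_mm disc_depth_mm
#> 1                10.25           1.8
as.data.frame(truth$truth_report)
#>   coronal_diameter_mm sagittal_diameter_mm medial_thickness_mm
#> 1                21.8                 22.4                10.5
#>   lateral_thickness_mm disc_depth_mm
#> 1                 10.5             2
```

The bone-only model misses the gold-standard surface by roughly the
cartilage thickness (0.73 mm RMS over the head); after compensation the
error drops to 0.26 mm, and the five morphometric parameters move to
within a voxel or two of the closed-form truth.

A full eight-specimen study — cohort generation, segmentation,
compensation, registration, morphometry and statistics — is one call:

```r
st <- runStudy(list(n = 8, cartilage_range = c(0.5, 2), seed = 1))
subset(st$stats, parameter == "coronal_diameter_mm")
#>             parameter     chi2 df            p         pair   p_adjusted
#>   coronal_diameter_mm 14.25 2 0.0008047310   gold vs ct 0.0005305037
#>   coronal_diameter_mm 14.25 2 0.0008047310 gold vs cirm 0.4008432076
#>   coronal_diameter_mm 14.25 2 0.0008047310   ct vs cirm 0.0733470519
```

The three model types differ (Friedman p < 0.01); the bone-only model
differs from the gold standard (adjusted p < 0.01) while the compensated
model does not — the qualitative pattern expected when the compensation
works.

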