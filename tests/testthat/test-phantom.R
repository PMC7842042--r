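# Synthetic elbow phantom: closed-form truth, rasterisation, cohorts.

test_that("truth report follows the closed-form geometry", {
  spec <- phantomSpec(headCoronalRadius = 9.9, rimCartilageT = 1.0)
  tr <- buildTruth(spec)
  rep <- as.data.frame(tr$truth_report)
  expect_equal(rep$coronal_diameter_mm, 21.8) # 2 * (9.9 + 1.0)
  expect_equal(rep$sagittal_diameter_mm, 2 * (10.2 + 1.0))
  expect_equal(rep$medial_thickness_mm, 10.5)
  expect_equal(rep$lateral_thickness_mm, 10.5)
  spec2 <- phantomSpec(dishDepth = 2.0)
  expect_equal(as.data.frame(buildTruth(spec2)$truth_report)$disc_depth_mm,
               2.0) # equal rim and dish cartilage cancel
  spec3 <- phantomSpec(rimCartilageT = 1.5, dishCartilageT = 0.75,
                       notchCartilageT = 1.5, capitellumCartilageT = 0.75)
  expect_equal(as.data.frame(buildTruth(spec3)$truth_report)$disc_depth_mm,
               2 + 1.5 - 0.75)
})

test_that("zero cartilage collapses bone and envelope surfaces", {
  spec <- phantomSpec(rimCartilageT = 0, dishCartilageT = 0,
                      notchCartilageT = 0, capitellumCartilageT = 0,
                      fluidGap = 1)
  tr <- buildTruth(spec)
  dv <- rmsDeviation(tr$bone_mesh, tr$cartilage_mesh)
  expect_lt(dv$rms, 0.2) # voxel-sampled bone vs analytic envelope
})

test_that("phantom spec validates its invariants", {
  expect_error(phantomSpec(rimCartilageT = 3.6), "0, 3.5")
  expect_error(phantomSpec(dishDepth = 30), "dishDepth")
  expect_error(phantomSpec(huBone = 100), "segmentation window")
  expect_error(phantomSpec(huCartilage = 400), "below the 250")
  expect_error(phantomSpec(nonsense = 1), "unknown phantom fields")
})

test_that("rasterisation is reproducible and keeps cartilage sub-threshold", {
  spec <- phantomSpec(spacing = c(0.4, 0.4, 0.6), seed = 77L)
  v1 <- rasterizePhantom(spec)
  v2 <- rasterizePhantom(spec)
  expect_identical(voxelData(v1), voxelData(v2))
  # cartilage at 80 HU never enters the bone mask
  mask <- thresholdBone(v1)
  spec0 <- phantomSpec(spacing = c(0.4, 0.4, 0.6), noiseSd = 0)
  v0 <- rasterizePhantom(spec0)
  cart <- voxelData(v0) > 60 & voxelData(v0) < 100
  m0 <- thresholdBone(v0)
  expect_equal(sum(voxelData(m0) & cart), 0L)
})

test_that("bone mask volume matches the analytic solid volume", {
  # circular head without tuberosity makes every part analytic
  spec <- phantomSpec(headCoronalRadius = 10, headSagittalRadius = 10,
                      tuberosityHeight = 0, noiseSd = 0)
  vol <- rasterizePhantom(spec)
  lab <- labelBones(thresholdBone(vol),
                    buildTruth(spec)$truth_landmarks$seed_points)
  vox <- sum(voxelData(lab) == 1L) * prod(voxelSpacing(lab))
  g <- ChondroCT:::phantomGeometry(spec)
  shaft <- pi * spec@neckRadius^2 * (g$z0h - (g$zlim[1] + 0.5 * 0.3))
  art_frac <- 170 / 360
  wall <- (g$Zb - g$z0h) *
    pi * (art_frac * 10^2 + (1 - art_frac) * 11^2)
  dish_cap <- pi * spec@dishDepth^2 *
    (spec@dishSphereRadius - spec@dishDepth / 3)
  analytic <- shaft + wall - dish_cap
  expect_equal(vox, analytic, tolerance = 0.02)
})

test_that("rasterisation converges as the voxel size shrinks", {
  # surface error of the voxel-sampled zero-cartilage solid against the
  # exact analytic envelope, at two resolutions
  surfErr <- function(sp) {
    spec <- phantomSpec(rimCartilageT = 0, dishCartilageT = 0,
                        notchCartilageT = 0, capitellumCartilageT = 0,
                        fluidGap = 1, noiseSd = 0, spacing = rep(sp, 3))
    tr <- buildTruth(spec)
    rmsDeviation(tr$bone_mesh, tr$cartilage_mesh)$rms
  }
  expect_lt(surfErr(0.2), surfErr(0.4) / 1.5)
})

test_that("cohorts are reproducible and bounded", {
  c1 <- generateCohort(n = 8, seed = 99L)
  c2 <- generateCohort(n = 8, seed = 99L)
  expect_equal(length(c1), 8L)
  f <- function(s) c(s@headCoronalRadius, s@rimCartilageT, s@dishCartilageT,
                     s@seed)
  expect_identical(lapply(c1, f), lapply(c2, f))
  expect_gt(length(unique(vapply(c1, function(s) s@rimCartilageT, 0))), 4)
  fixed <- generateCohort(n = 3, cartilage_range = c(1, 1),
                          dish_to_rim = c(1, 1), seed = 5L)
  for (s in fixed) {
    expect_equal(s@rimCartilageT, 1.0)
    expect_equal(s@dishCartilageT, 1.0)
    expect_equal(s@notchCartilageT, 1.0)
    expect_equal(s@capitellumCartilageT, 1.0)
  }
  expect_error(generateCohort(cartilage_range = c(0.5, 4)), "3.5")
})

test_that("truth report agrees with morphometry of the gold mesh", {
  run <- defaultPhantomRun()
  frame <- referenceFrame(run$truth$cartilage_mesh,
                          run$truth$truth_landmarks$tuberosity_point)
  got <- as.data.frame(suppressWarnings(
    measureAll(run$truth$cartilage_mesh, frame)))
  want <- as.data.frame(run$truth$truth_report)
  half_voxel <- max(run$spec@spacing) / 2
  for (p in names(want))
    expect_lt(abs(got[[p]] - want[[p]]), half_voxel + 1e-9)
})
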