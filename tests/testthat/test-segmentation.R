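# Hounsfield thresholding, seeded labelling, slice contours and isosurfaces.

test_that("bone threshold uses inclusive bounds and validates the window", {
  vol <- CTVolume(array(c(249, 250, 2500, 2501, -1000, 700, 30, 80),
                        c(2, 2, 2)))
  m <- thresholdBone(vol)
  expect_equal(as.logical(voxelData(m)),
               c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_error(thresholdBone(vol, 500, 500), "strictly below")
  air <- thresholdBone(CTVolume(array(-1000, c(3, 3, 3))))
  expect_false(any(voxelData(air)))
})

test_that("threshold is idempotent and monotone in the HU window", {
  set.seed(7)
  vol <- CTVolume(array(runif(1000, -500, 3000), c(10, 10, 10)))
  narrow <- thresholdBone(vol, 400, 2000)
  wide <- thresholdBone(vol, 250, 2500)
  expect_true(all(voxelData(wide)[voxelData(narrow)]))
  again <- thresholdBone(CTVolume(voxelData(vol)), 400, 2000)
  expect_identical(voxelData(again), voxelData(narrow))
})

test_that("seeded labelling separates disjoint bones and validates seeds", {
  arr <- array(FALSE, c(20, 10, 10))
  arr[2:5, 2:9, 2:9] <- TRUE     # block 1: 4*8*8 = 256 voxels
  arr[8:12, 2:6, 2:6] <- TRUE    # block 2: 5*5*5 = 125
  arr[15:19, 3:7, 3:8] <- TRUE   # block 3: 5*5*6 = 150
  m <- BinaryMask(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  lab <- labelBones(m, list(radius = c(3, 5, 5), ulna = c(9, 3, 3),
                            humerus = c(16, 5, 5)))
  counts <- tabulate(voxelData(lab)[voxelData(lab) > 0], 3)
  expect_equal(counts, c(256L, 125L, 150L))
  one <- labelBones(m, list(radius = c(3, 5, 5)))
  expect_equal(sum(voxelData(one) == 1L), 256L)
  expect_error(labelBones(m, list(radius = c(6.5, 5, 5))), "background")
  expect_error(labelBones(m, list(radius = c(3, 5, 5), ulna = c(4, 5, 5))),
               "same connected component")
})

test_that("axial contours trace the outer boundary with shoelace area", {
  arr <- array(FALSE, c(15, 15, 3))
  arr[3:13, 3:13, 2] <- TRUE # 11 x 11 square, 1 mm spacing
  m <- BinaryMask(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  ctr <- extractAxialContour(m, "radius", 2)
  expect_gt(polygonArea(ctr@points), 0) # counter-clockwise
  expect_equal(polygonArea(ctr@points), 121, tolerance = 1 / 121)
  # single voxel: a small loop of roughly one voxel area
  arr1 <- array(FALSE, c(5, 5, 1)); arr1[3, 3, 1] <- TRUE
  m1 <- BinaryMask(arr1, spacing = c(0.5, 0.5, 1), origin = c(0, 0, 0))
  c1 <- extractAxialContour(m1, "radius", 1)
  expect_equal(polygonArea(c1@points), 0.25, tolerance = 0.6)
  expect_error(extractAxialContour(m, "radius", 1), "absent")
})

test_that("contour area matches voxel count within a perimeter row", {
  set.seed(11)
  arr <- array(FALSE, c(40, 40, 1))
  cx <- 20.5; cy <- 19.5
  for (i in 1:40) for (j in 1:40)
    arr[i, j, 1] <- (i - cx)^2 + (j - cy)^2 <= 13^2
  m <- BinaryMask(arr, spacing = c(0.5, 0.5, 1), origin = c(0, 0, 0))
  ctr <- extractAxialContour(m, "radius", 1)
  nvox <- sum(arr)
  area <- polygonArea(ctr@points)
  perim_row <- 2 * pi * 13 * 0.5 * 0.5 # one voxel-wide ring, mm^2
  expect_lt(abs(area - nvox * 0.25), perim_row)
})

test_that("largest-loop rule returns the outer boundary of a hollow section", {
  arr <- array(FALSE, c(30, 30, 1))
  for (i in 1:30) for (j in 1:30) {
    r2 <- (i - 15.5)^2 + (j - 15.5)^2
    arr[i, j, 1] <- r2 <= 12^2 && r2 >= 6^2 # annulus
  }
  m <- BinaryMask(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  ctr <- extractAxialContour(m, "radius", 1)
  expect_equal(polygonArea(ctr@points), pi * 12^2, tolerance = 0.05)
})

test_that("isosurface of a rasterised sphere stays within a voxel of truth", {
  m <- sphereMask(r = 10, spacing = 0.2)
  mesh <- meshFromMask(m)
  expect_true(isWatertight(mesh))
  d <- abs(sqrt(rowSums(meshVertices(mesh)^2)) - 10)
  expect_lte(max(d), 0.2)
  expect_equal(meshVolume(mesh), 4 / 3 * pi * 1000, tolerance = 0.01)
})

test_that("isosurface handles single voxels and empty masks", {
  arr <- array(FALSE, c(3, 3, 3)); arr[2, 2, 2] <- TRUE
  m <- BinaryMask(arr, spacing = c(0.3, 0.3, 0.3), origin = c(0, 0, 0))
  mesh <- meshFromMask(m)
  expect_true(isWatertight(mesh))
  expect_equal(meshVolume(mesh), 0.027, tolerance = 0.5)
  arr[2, 2, 2] <- FALSE
  expect_error(meshFromMask(BinaryMask(arr, c(1, 1, 1), c(0, 0, 0))),
               "empty")
})

test_that("isosurface volume error shrinks with voxel size", {
  errAt <- function(sp) {
    m <- sphereMask(r = 5, spacing = sp)
    abs(meshVolume(meshFromMask(m)) - 4 / 3 * pi * 125)
  }
  coarse <- errAt(0.5)
  fine <- errAt(0.25)
  expect_lt(fine, coarse / 1.5)
})
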