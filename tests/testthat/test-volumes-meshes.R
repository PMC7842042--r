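# Volume and mesh I/O, grid geometry and the rigid-transform container.

test_that("voxel grid maps indices to physical coordinates (centre convention)", {
  vol <- CTVolume(array(0, c(4, 5, 6)), spacing = c(0.2, 0.2, 0.3),
                  origin = c(1, 2, 3))
  ijk <- rbind(c(0, 0, 0), c(3, 4, 5), c(1, 2, 3))
  expect_equal(voxelToWorld(vol, ijk),
               cbind(1 + ijk[, 1] * 0.2, 2 + ijk[, 2] * 0.2,
                     3 + ijk[, 3] * 0.3))
  expect_equal(worldToVoxel(vol, voxelToWorld(vol, ijk)), ijk)
  expect_error(CTVolume(array(0, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "spacing")
  expect_error(CTVolume(array(c(1, NA, 1, 1, 1, 1, 1, 1), c(2, 2, 2))),
               "finite")
})

test_that("NIfTI volumes round-trip with spacing and origin", {
  vol <- CTVolume(array(rnorm(4 * 5 * 6, 100, 300), c(4, 5, 6)),
                  spacing = c(0.2, 0.2, 0.3), origin = c(-3, 1.5, 7))
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(vol, f)
  back <- readVolume(f)
  expect_equal(voxelData(back), voxelData(vol), tolerance = 1e-6)
  expect_equal(voxelSpacing(back), voxelSpacing(vol), tolerance = 1e-6)
  expect_equal(voxelOrigin(back), voxelOrigin(vol), tolerance = 1e-6)
})

test_that("DICOM series reader applies rescale and assembles geometry", {
  d <- writeDicomSeries(tempfile("dcm"), nslices = 4, rows = 6, cols = 5,
                        dz = 0.3, slope = 1, intercept = -1024,
                        value = 1274L)
  vol <- readVolume(d)
  expect_equal(dim(voxelData(vol)), c(5L, 6L, 4L))
  # stored 1274+k, slope 1, intercept -1024 -> HU 250+k per slice
  expect_equal(voxelData(vol)[1, 1, 1], 251)
  expect_equal(voxelData(vol)[3, 2, 4], 254)
  # PixelSpacing is (row, column) = (dy, dx)
  expect_equal(voxelSpacing(vol), c(0.2, 0.25, 0.3))
  expect_equal(voxelOrigin(vol), c(0, 0, 0))
})

test_that("DICOM series with a missing slice names the gap", {
  d <- writeDicomSeries(tempfile("dcm"), nslices = 5, skip = 3)
  expect_error(readVolume(d), "inconsistent DICOM slice spacing.*slice 2")
})

test_that("oblique DICOM orientations are rejected", {
  d <- writeDicomSeries(tempfile("dcm"), nslices = 3,
                        orientation = c(0.99, 0.14, 0, -0.14, 0.99, 0))
  expect_error(readVolume(d), "oblique")
})

test_that("hand-written ASCII STL cube welds to 8 vertices and 12 faces", {
  cube <- readMesh(test_path("fixtures", "cube-ascii.stl"))
  expect_equal(nrow(meshVertices(cube)), 8L)
  expect_equal(nrow(meshFaces(cube)), 12L)
  expect_true(isWatertight(cube))
  expect_equal(abs(meshVolume(cube)), 1, tolerance = 1e-12)
})

test_that("STL dialects and PLY round-trip the same geometry", {
  cube <- readMesh(test_path("fixtures", "cube-ascii.stl"))
  sortv <- function(m) m[do.call(order, asplit(m, 2)), ]
  for (fmt in c("stl-binary", "stl-ascii")) {
    f <- tempfile(fileext = ".stl")
    writeMesh(cube, f, fmt)
    back <- readMesh(f)
    expect_equal(sortv(meshVertices(back)), sortv(meshVertices(cube)),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(nrow(meshFaces(back)), 12L)
  }
  dev <- new("TriMesh", vertices = meshVertices(cube),
             faces = meshFaces(cube),
             vertexScalar = seq_len(8) / 7)
  f <- tempfile(fileext = ".ply")
  writeMesh(dev, f, "ply")
  back <- readMesh(f)
  expect_equal(vertexScalar(back), vertexScalar(dev), tolerance = 1e-6)
  expect_equal(meshVertices(back), meshVertices(dev), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("malformed mesh files and empty meshes raise errors", {
  f <- tempfile(fileext = ".stl")
  con <- file(f, "wb")
  writeBin(raw(60), con) # shorter than the 84-byte binary header
  close(con)
  expect_error(readMesh(f, "stl-binary"), "truncated")
  f2 <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 10"), f2)
  expect_error(readMesh(f2, "ply"), "end_header")
  empty <- new("TriMesh", vertices = matrix(0, 0, 3),
               faces = matrix(0L, 0, 3), vertexScalar = NULL)
  expect_error(writeMesh(empty, tempfile(), "stl-binary"), "empty")
})

test_that("rigid transforms are validated, composed and applied", {
  th <- 0.3
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- RigidTransform(R, c(1, 2, 3))
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(applyTransform(tr, p), t(R %*% t(p)) + rep(c(1, 2, 3), each = 10))
  tr2 <- composeTransform(tr, tr)
  expect_equal(applyTransform(tr2, p),
               applyTransform(tr, applyTransform(tr, p)))
  expect_error(RigidTransform(matrix(1, 3, 3)), "orthonormal")
  Rflip <- diag(c(1, 1, -1))
  expect_error(RigidTransform(Rflip), "det")
})
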