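# Region selection, rigid ICP and RMS surface deviation.

# Deterministic bumpy closed test surface (icosphere-style sphere mesh via
# voxelisation keeps everything in-package).
testSphereMesh <- function(r = 6, spacing = 0.4) meshFromMask(sphereMask(r, spacing))

test_that("region selection honours plane side and explicit ids", {
  mesh <- testSphereMesh()
  above_all <- RegionSpec(plane = list(point = c(0, 0, 100), normal = c(0, 0, 1)))
  expect_equal(length(selectRegion(mesh, above_all)),
               nrow(meshVertices(mesh)))
  below_all <- RegionSpec(plane = list(point = c(0, 0, -100), normal = c(0, 0, 1)))
  expect_error(selectRegion(mesh, below_all), "empty")
  half <- RegionSpec(plane = list(point = c(0, 0, 0), normal = c(0, 0, 1)))
  ids <- selectRegion(mesh, half)
  expect_true(all(meshVertices(mesh)[ids, 3] < 0))
  byid <- RegionSpec(ids = c(1L, 5L, 9L))
  expect_equal(selectRegion(mesh, byid), c(1L, 5L, 9L))
  expect_error(selectRegion(mesh, RegionSpec(ids = 10^7)), "out of range")
  expect_error(RegionSpec(), "exactly one")
})

test_that("ICP returns the identity for identical meshes", {
  mesh <- testSphereMesh()
  region <- RegionSpec(plane = list(point = c(0, 0, 2), normal = c(0, 0, 1)))
  tr <- icpRigid(mesh, mesh, region)
  expect_equal(tr@rotation, diag(3), tolerance = 1e-9)
  expect_equal(tr@translation, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(attr(tr, "rms"), 1e-9)
})

test_that("ICP rejects degenerate regions", {
  mesh <- testSphereMesh()
  expect_error(icpRigid(mesh, mesh, RegionSpec(ids = c(1L, 2L))),
               "degenerate region")
})

test_that("RMS deviation matches analytic offsets and brute force", {
  mesh <- testSphereMesh(r = 4, spacing = 0.5)
  expect_equal(rmsDeviation(mesh, mesh)$rms, 0, tolerance = 1e-12)
  # dense planar patch against the same patch offset along its normal
  g <- seq(0, 10, by = 0.25)
  verts <- as.matrix(expand.grid(x = g, y = g))
  nxy <- length(g)
  idx <- function(i, j) (j - 1L) * nxy + i
  i <- rep(1:(nxy - 1), nxy - 1); j <- rep(1:(nxy - 1), each = nxy - 1)
  faces <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                 cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  patch <- TriMesh(cbind(verts, 0), faces)
  lifted <- TriMesh(cbind(verts, 0.3), faces)
  expect_equal(rmsDeviation(lifted, patch)$rms, 0.3, tolerance = 1e-6)
  # one displaced vertex of an N-vertex mesh: rms = d / sqrt(N)
  v2 <- meshVertices(patch); n_v <- nrow(v2)
  v2[idx(20, 20), 3] <- 0.2 # interior vertex lifted by d = 0.2
  moved <- TriMesh(v2, faces)
  d_expect <- 0.2 / sqrt(n_v)
  # brute-force oracle: exhaustive point-to-triangle scan
  brute <- vapply(seq_len(n_v), function(k) {
    p <- v2[k, ]
    min(vapply(seq_len(nrow(faces)), function(f) {
      tri <- meshVertices(patch)[faces[f, ], ]
      r <- ChondroCT:::.cct_nearest_on_surface(matrix(p, 1), tri,
                                               matrix(1:3, 1))
      r$distance
    }, 0))
  }, 0)
  got <- rmsDeviation(moved, patch)
  expect_equal(got$rms, sqrt(mean(brute^2)), tolerance = 1e-9)
  expect_lte(got$rms, d_expect + 1e-9) # nearest surface cuts the corner
  expect_equal(vertexScalar(got$mesh), brute, tolerance = 1e-9)
})

test_that("RMS deviation is invariant under a common rigid transform", {
  a <- testSphereMesh(r = 4, spacing = 0.5)
  v <- meshVertices(a); v[, 3] <- v[, 3] * 1.04
  b <- TriMesh(v, meshFaces(a))
  base <- rmsDeviation(a, b)$rms
  th <- 0.7
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  tr <- RigidTransform(R, c(4, -2, 9))
  moved <- rmsDeviation(applyTransform(tr, a), applyTransform(tr, b))$rms
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("nearest distances equal an exhaustive scan on small meshes", {
  set.seed(42)
  mesh <- testSphereMesh(r = 3, spacing = 0.8)
  expect_lte(nrow(meshVertices(mesh)), 500 * 3) # small enough to scan
  pts <- matrix(rnorm(60, sd = 3), 20, 3)
  fast <- ChondroCT:::.cct_nearest_on_surface(pts, meshVertices(mesh),
                                              meshFaces(mesh))
  slow <- vapply(seq_len(nrow(pts)), function(k) {
    min(vapply(seq_len(nrow(meshFaces(mesh))), function(f) {
      ChondroCT:::.cct_nearest_on_surface(
        pts[k, , drop = FALSE],
        meshVertices(mesh)[meshFaces(mesh)[f, ], ],
        matrix(1:3, 1))$distance
    }, 0))
  }, 0)
  expect_equal(fast$distance, slow, tolerance = 1e-12)
})
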