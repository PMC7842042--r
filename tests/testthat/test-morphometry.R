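# Rim extraction, reference planes and the five radial-head parameters.

test_that("best-fit plane recovers flat and tilted point sets", {
  g <- expand.grid(x = 0:10, y = 0:10)
  flat <- bestFitPlane(cbind(g$x, g$y, 5))
  expect_equal(flat$normal, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(flat$point[3], 5, tolerance = 1e-9)
  # rim circle tilted by 10 degrees about y
  th <- 10 * pi / 180
  ang <- seq(0, 2 * pi, length.out = 73)[-1]
  ring <- cbind(10 * cos(ang), 10 * sin(ang), 0)
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  tilted <- bestFitPlane(t(R %*% t(ring)))
  expect_equal(abs(sum(tilted$normal * (R %*% c(0, 0, 1)))), 1,
               tolerance = 1e-6)
  expect_error(bestFitPlane(rbind(c(0, 0, 0), c(1, 1, 1))), "at least 3")
  expect_error(bestFitPlane(cbind(1:9, 2 * (1:9), 3 * (1:9))), "collinear")
})

test_that("head-neck vertex maximises chord distance with first-point ties", {
  ang <- seq(pi, 0, length.out = 181)
  semi <- cbind(5 * cos(ang), 5 * sin(ang))
  expect_equal(headneckVertex(semi), c(0, 5), tolerance = 1e-9)
  x <- seq(-1, 1, by = 0.01)
  parab <- cbind(x, 1 - x^2)
  # brute-force oracle over the sampled curve
  a <- parab[1, ]; b <- parab[nrow(parab), ]
  d <- abs((b[1] - a[1]) * (a[2] - parab[, 2]) -
             (a[1] - parab[, 1]) * (b[2] - a[2])) /
    sqrt(sum((b - a)^2))
  expect_equal(headneckVertex(parab), unname(parab[which.max(d), ]))
  expect_equal(headneckVertex(parab), c(0, 1), tolerance = 1e-9)
  expect_error(headneckVertex(cbind(0:10, 0)), "straight")
})

test_that("articular rim of a flat-topped cylinder is the top edge circle", {
  arr <- array(FALSE, c(40, 40, 20))
  for (i in 1:40) for (j in 1:40)
    arr[i, j, 1:15] <- (i - 20.5)^2 + (j - 20.5)^2 <= 15^2
  mesh <- meshFromMask(BinaryMask(arr, c(0.5, 0.5, 0.5), c(0, 0, 0)))
  rim <- articularRim(mesh, c(0, 0, 1))
  cen <- colMeans(meshVertices(mesh))
  rr <- sqrt((rim[, 1] - cen[1])^2 + (rim[, 2] - cen[2])^2)
  expect_equal(stats::median(rr), 7.5, tolerance = 0.3)
  expect_lt(diff(range(rim[, 3])), 0.51) # all on the top edge
  expect_warning(articularRim(meshFromMask(sphereMask(5, 0.5)), c(0, 0, 1)),
                 "degenerate rim")
})

test_that("disc centre picks the deepest dish point with centroid ties", {
  # flat top: all candidate depths tie at zero -> centroid of the top face
  arr <- array(FALSE, c(30, 30, 12))
  for (i in 1:30) for (j in 1:30)
    arr[i, j, 1:10] <- (i - 15.5)^2 + (j - 15.5)^2 <= 11^2
  mesh <- meshFromMask(BinaryMask(arr, c(0.5, 0.5, 0.5), c(0, 0, 0)))
  rim <- articularRim(mesh, c(0, 0, 1))
  pl <- bestFitPlane(rim)
  dc <- discCenter(mesh, pl, rim = rim)
  expect_equal(dc[1:2], c(7.25, 7.25), tolerance = 0.2)
  expect_equal(dc[3], 4.75, tolerance = 0.26)
  # convex cap only: nothing below the rim plane within the dish bound
  sph <- meshFromMask(sphereMask(5, 0.5))
  rim_s <- suppressWarnings(articularRim(sph, c(0, 0, 1)))
  expect_error(discCenter(sph, bestFitPlane(rim_s), rim = rim_s),
               "below the rim plane")
})

test_that("diameters of voxelised analytic solids are exact chords", {
  run <- defaultPhantomRun()
  frame <- referenceFrame(run$truth$cartilage_mesh,
                          run$truth$truth_landmarks$tuberosity_point)
  # voxelised sphere r = 11 measured at its equator
  sph <- meshFromMask(sphereMask(11, 0.2))
  fr_s <- new("ReferenceFrame", discCenter = c(0, 0, 0),
              coronalNormal = c(0, 1, 0), sagittalNormal = c(-1, 0, 0),
              axialNormal = c(0, 0, 1), axialLevel = 0,
              junctionLine = list())
  d <- headDiameters(sph, fr_s)
  expect_equal(unname(d["coronal"]), 22, tolerance = 0.2 / 22)
  expect_equal(unname(d["sagittal"]), 22, tolerance = 0.2 / 22)
  # elliptic cylinder, semi-axes 11 and 10.5 aligned with the frame
  arr <- array(FALSE, c(120, 116, 12))
  xg <- ((1:120) - 60.5) * 0.2; yg <- ((1:116) - 58.5) * 0.2
  sl <- outer(xg^2 / 11^2, yg^2 / 10.5^2, `+`) <= 1
  for (k in 2:11) arr[, , k] <- sl
  ell <- meshFromMask(BinaryMask(arr, c(0.2, 0.2, 0.5),
                                 c(xg[1], yg[1], 0)))
  fr_e <- new("ReferenceFrame", discCenter = c(0, 0, 0),
              coronalNormal = c(0, 1, 0), sagittalNormal = c(-1, 0, 0),
              axialNormal = c(0, 0, 1), axialLevel = 3,
              junctionLine = list())
  de <- headDiameters(ell, fr_e)
  expect_equal(unname(de["coronal"]), 22, tolerance = 0.2 / 22)
  expect_equal(unname(de["sagittal"]), 21, tolerance = 0.2 / 21)
  fr_hi <- fr_e; fr_hi@axialLevel <- 50
  expect_error(headDiameters(ell, fr_hi), "empty cross-section")
})

test_that("the reference frame is orthonormal with the tuberosity in the coronal plane", {
  run <- defaultPhantomRun()
  lm <- run$truth$truth_landmarks
  frame <- referenceFrame(run$truth$cartilage_mesh, lm$tuberosity_point)
  B <- cbind(frame@coronalNormal, frame@sagittalNormal, frame@axialNormal)
  expect_equal(crossprod(B), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(det(B), 1, tolerance = 1e-9)
  # tuberosity bump sits at azimuth 180: the coronal plane contains the
  # x axis, so its normal is orthogonal to (1, 0, 0)
  expect_lt(abs(sum(frame@coronalNormal * c(1, 0, 0))), 1e-6)
  expect_error(referenceFrame(run$truth$cartilage_mesh,
                              lm$tuberosity_point + c(0, 5, 0)),
               "off the surface")
})

test_that("measurements are invariant under a common rigid transform", {
  run <- defaultPhantomRun()
  lm <- run$truth$truth_landmarks
  mesh <- run$cir$ct_mesh
  frame <- referenceFrame(run$truth$cartilage_mesh, lm$tuberosity_point)
  base <- as.data.frame(suppressWarnings(measureAll(mesh, frame)))
  th <- 0.5
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  tr <- RigidTransform(R, c(10, -4, 2))
  mesh2 <- applyTransform(tr, mesh)
  frame2 <- new("ReferenceFrame",
                discCenter = as.numeric(applyTransform(tr, matrix(frame@discCenter, 1))),
                coronalNormal = as.numeric(R %*% frame@coronalNormal),
                sagittalNormal = as.numeric(R %*% frame@sagittalNormal),
                axialNormal = as.numeric(R %*% frame@axialNormal),
                axialLevel = frame@axialLevel +
                  sum((R %*% frame@axialNormal) * tr@translation),
                junctionLine = list(
                  point = as.numeric(applyTransform(tr, matrix(frame@junctionLine$point, 1))),
                  direction = as.numeric(R %*% frame@junctionLine$direction)))
  moved <- as.data.frame(suppressWarnings(measureAll(mesh2, frame2)))
  expect_equal(moved, base, tolerance = 1e-6)
})

test_that("measurements scale linearly with the mesh and frame", {
  run <- defaultPhantomRun()
  lm <- run$truth$truth_landmarks
  gold <- run$truth$cartilage_mesh
  frame <- referenceFrame(gold, lm$tuberosity_point)
  base <- as.data.frame(suppressWarnings(measureAll(gold, frame)))
  s <- 1.3
  scaled_mesh <- new("TriMesh", vertices = meshVertices(gold) * s,
                     faces = meshFaces(gold), vertexScalar = NULL)
  frame_s <- frame
  frame_s@discCenter <- frame@discCenter * s
  frame_s@axialLevel <- frame@axialLevel * s
  frame_s@junctionLine$point <- frame@junctionLine$point * s
  scaled <- as.data.frame(suppressWarnings(measureAll(scaled_mesh, frame_s)))
  expect_equal(as.numeric(scaled), as.numeric(base) * s, tolerance = 1e-6)
})
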