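# Slice-level cartilage compensation: circle fit, junction detection,
# reforming axis, gap measurement and the contour reform.

circlePoints <- function(cx, cy, r, n = 120, from = 0, to = 360) {
  ang <- seq(from, to, length.out = n) * pi / 180
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

test_that("reference circle fit recovers exact circles and rejects lines", {
  p <- circlePoints(3, 4, 10, n = 90, to = 357)
  fit <- fitReferenceCircle(p)
  expect_equal(fit$center, c(3, 4), tolerance = 1e-9)
  expect_equal(fit$radius, 10, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-9)
  expect_error(fitReferenceCircle(cbind(1:5, 2 * (1:5))), ".")
  expect_error(fitReferenceCircle(cbind(1:20, 2 * (1:20) + 3)), "collinear")
})

test_that("circle fit with the altered sector excluded recovers the original", {
  ang <- seq(0, 359, by = 1.5) * pi / 180
  p <- cbind(2 + 8 * cos(ang), -1 + 8 * sin(ang))
  # replace the 0..60 degree sector by its chord
  deg <- (ang * 180 / pi)
  inside <- deg >= 0 & deg <= 60
  a <- c(2 + 8, -1); b <- c(2 + 8 * cos(pi / 3), -1 + 8 * sin(pi / 3))
  tfrac <- (deg[inside] - 0) / 60
  p[inside, ] <- cbind(a[1] + tfrac * (b[1] - a[1]),
                       a[2] + tfrac * (b[2] - a[2]))
  fit <- fitReferenceCircle(p, exclusion = c(-3, 63))
  expect_equal(fit$center, c(2, -1), tolerance = 1e-6)
  expect_equal(fit$radius, 8, tolerance = 1e-6)
})

test_that("ANA junctions are found where the articular recession starts", {
  ctr <- recessedContour(R = 10, t = 1, a1 = -30, a2 = 30, n = 720)
  jn <- detectAnaJunctions(ctr, c(1, 0), deviation_tol = 0.2)
  angs <- sort(c(atan2(jn@j1[2], jn@j1[1]), atan2(jn@j2[2], jn@j2[1])) *
                 180 / pi)
  expect_equal(angs[1], -30, tolerance = 3)
  expect_equal(angs[2], 30, tolerance = 3)
  expect_equal(sum(jn@articularSide * c(1, 0)), 1, tolerance = 1e-6)
})

test_that("contours without articular alteration are rejected", {
  perfect <- SliceContour(circlePoints(0, 0, 10, n = 360, to = 359))
  expect_error(detectAnaJunctions(perfect, c(1, 0), deviation_tol = 0.2),
               "no articular alteration")
  shallow <- recessedContour(R = 10, t = 0.1, n = 360)
  expect_error(detectAnaJunctions(shallow, c(1, 0), deviation_tol = 0.2),
               "no articular alteration")
})

test_that("reforming axis is the oriented chord-midpoint perpendicular", {
  jp <- new("ANAJunctionPair", j1 = c(0, 10), j2 = c(0, -10),
            articularSide = c(1, 0), i1 = 1L, i2 = 2L,
            center = c(0, 0), radius = 10)
  ax <- reformingAxis(jp)
  expect_equal(ax@origin, c(0, 0))
  expect_equal(ax@direction, c(1, 0))
  jp2 <- new("ANAJunctionPair", j1 = c(1, 1), j2 = c(3, 1),
             articularSide = c(0, -1), i1 = 1L, i2 = 2L,
             center = c(2, 5), radius = 4)
  ax2 <- reformingAxis(jp2)
  expect_equal(ax2@origin, c(2, 1))
  expect_equal(ax2@direction, c(0, -1))
  expect_error(new("ANAJunctionPair", j1 = c(1, 1), j2 = c(1, 1),
                   articularSide = c(1, 0), i1 = 1L, i2 = 2L,
                   center = c(0, 0), radius = 1), "distinct")
  jp3 <- new("ANAJunctionPair", j1 = c(0, 0), j2 = c(0.05, 0),
             articularSide = c(0, 1), i1 = 1L, i2 = 2L,
             center = c(0, -3), radius = 3)
  expect_error(reformingAxis(jp3, inplane_voxel = 0.2), "degenerate chord")
})

test_that("subchondral gap is the head-to-opposing distance along the ray", {
  sq <- function(x0, x1, y0, y1)
    SliceContour(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)))
  head_c <- sq(-10, 10, -10, 10)
  opp <- sq(14, 20, -5, 5)
  ax <- new("ReformingAxis", origin = c(0, 0), direction = c(1, 0))
  gm <- subchondralGap(head_c, opp, ax)
  expect_equal(gm@gap, 4)
  expect_equal(gm@pointOnHead, c(10, 0))
  expect_equal(gm@pointOnOpposing, c(14, 0))
  touching <- sq(10, 20, -5, 5)
  expect_equal(subchondralGap(head_c, touching, ax)@gap, 0)
  off_axis <- sq(14, 20, 5, 9)
  expect_error(subchondralGap(head_c, off_axis, ax), "not apposed")
})

test_that("gap across cartilage and fluid layers sums analytically", {
  # head bone recessed 1 mm (its cartilage), 0.5 mm fluid, 1 mm ulnar
  # cartilage: subchondral gap along the reforming axis = 2.5 mm
  ctr <- recessedContour(R = 10, t = 1, a1 = -40, a2 = 40, n = 720)
  ang <- seq(-50, 50, by = 0.5) * pi / 180
  inner <- 10 + 0.5 + 1 # envelope + fluid + ulnar cartilage
  opp <- SliceContour(rbind(
    cbind(inner * cos(ang), inner * sin(ang)),
    cbind((inner + 6) * cos(rev(ang)), (inner + 6) * sin(rev(ang)))))
  jn <- detectAnaJunctions(ctr, c(1, 0), deviation_tol = 0.2)
  ax <- reformingAxis(jn)
  gm <- subchondralGap(ctr, opp, ax)
  expect_equal(gm@gap, 2.5, tolerance = 0.05)
})

test_that("reform translates the articular arc and fills over the junctions", {
  ctr <- recessedContour(R = 10, t = 1, a1 = -30, a2 = 30, n = 720)
  jn <- detectAnaJunctions(ctr, c(1, 0), deviation_tol = 0.2)
  ax <- reformingAxis(jn)
  same <- reformSlice(ctr, jn, ax, 0)
  expect_equal(same@points, ctr@points)
  out <- reformSlice(ctr, jn, ax, 2)
  # articular vertices strictly between the junctions move by exactly
  # 2 mm along the axis; nonarticular vertices are untouched
  ang <- atan2(ctr@points[, 2], ctr@points[, 1]) * 180 / pi
  art <- abs(ang) < 25
  non <- abs(ang) > 40
  op <- out@points
  key <- function(m) paste(round(m[, 1], 9), round(m[, 2], 9))
  shifted <- sweep(ctr@points[art, ], 2, -2 * ax@direction)
  expect_true(all(key(shifted) %in% key(op)))
  expect_true(all(key(ctr@points[non, ]) %in% key(op)))
  expect_gte(polygonArea(op), polygonArea(ctr@points))
})

test_that("reform area growth matches a swept-region rasterisation oracle", {
  ctr <- recessedContour(R = 10, t = 1, a1 = -35, a2 = 35, n = 720)
  jn <- detectAnaJunctions(ctr, c(1, 0), deviation_tol = 0.2)
  ax <- reformingAxis(jn)
  delta <- 1.4
  out <- reformSlice(ctr, jn, ax, delta)
  # oracle: union of the input polygon with the region swept by the
  # articular path, counted on a fine pixel grid
  grid_fill <- function(poly) {
    ChondroCT:::.cct_polygon_fill(poly, -11, -11, 0.02, 0.02, 1101, 1101)
  }
  n <- nrow(ctr@points)
  start <- which.min(ctr@points %*% ax@direction)
  art <- ChondroCT:::articularIndexRange(n, jn@i1, jn@i2, start)
  path <- ctr@points[art, ]
  ribbon <- rbind(path, sweep(path[nrow(path):1, ], 2, -delta * ax@direction))
  union_px <- grid_fill(ctr@points) | grid_fill(ribbon)
  out_px <- grid_fill(out@points)
  a_union <- sum(union_px) * 0.02^2
  a_out <- sum(out_px) * 0.02^2
  expect_equal(a_out, a_union, tolerance = 0.01)
})
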