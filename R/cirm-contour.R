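# Slice-level geometry of the cartilage compensation: reference-circle fit,
# articular/nonarticular (ANA) junction detection, reforming axis,
# subchondral gap measurement and the contour reform itself.

#' ANAJunctionPair: articular-nonarticular junctions on a slice contour
#'
#' The two points where the circular nonarticular boundary of the radial
#' head transitions into the recessed articular (cartilage-covered)
#' subchondral boundary.
#'
#' @slot j1,j2 length-2 mm points on the contour.
#' @slot articularSide unit 2-D direction from the chord toward the
#'   articular portion.
#' @slot i1,i2 indices of the junctions in the source contour.
#' @slot center,radius reference circle fitted to the nonarticular portion.
#' @aliases ANAJunctionPair
#' @export
setClass("ANAJunctionPair",
  representation(j1 = "numeric", j2 = "numeric", articularSide = "numeric",
                 i1 = "integer", i2 = "integer",
                 center = "numeric", radius = "numeric"),
  validity = function(object) {
    if (sqrt(sum((object@j1 - object@j2)^2)) < 1e-12)
      return("junctions must be distinct points")
    TRUE
  })

#' ReformingAxis: translation axis of the articular portion
#'
#' The perpendicular through the midpoint of the chord between the two ANA
#' junctions, oriented toward the articular side.
#'
#' @slot origin length-2 mm point (chord midpoint).
#' @slot direction unit 2-D vector, perpendicular to the chord.
#' @aliases ReformingAxis
#' @export
setClass("ReformingAxis",
  representation(origin = "numeric", direction = "numeric"),
  validity = function(object) {
    if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
      return("direction must be a unit vector")
    TRUE
  })

#' GapMeasurement: subchondral gap along the reforming axis
#'
#' @slot gap distance (mm, `>= 0`) between the two subchondral surfaces.
#' @slot pointOnHead,pointOnOpposing points where the measuring ray meets
#'   each subchondral boundary.
#' @aliases GapMeasurement
#' @export
setClass("GapMeasurement",
  representation(gap = "numeric", pointOnHead = "numeric",
                 pointOnOpposing = "numeric"),
  validity = function(object) {
    d <- sqrt(sum((object@pointOnHead - object@pointOnOpposing)^2))
    if (object@gap < 0) return("gap must be >= 0")
    if (abs(d - object@gap) > 1e-6)
      return("gap must equal the distance between the two surface points")
    TRUE
  })

#' Least-squares circle through contour points
#'
#' Fits a circle to the contour points outside an optional exclusion, by
#' linear least squares on the algebraic circle equation.  Used to model the
#' circular nonarticular portion of the radial head cross-section.
#'
#' @param contour a [SliceContour-class] or an `n x 2` point matrix.
#' @param exclusion `NULL`, a logical vector marking points to exclude, or
#'   a numeric `c(from_deg, to_deg)` angular sector (degrees, measured at
#'   the point centroid, counter-clockwise from +x) to exclude.
#' @return list with `center` (length-2), `radius`, and `rms_residual`
#'   (root-mean-square radial misfit of the points used).
#' @export
fitReferenceCircle <- function(contour, exclusion = NULL) {
  p <- if (is(contour, "SliceContour")) contour@points else as.matrix(contour)
  keep <- rep(TRUE, nrow(p))
  if (is.logical(exclusion)) {
    keep <- !exclusion
  } else if (is.numeric(exclusion) && length(exclusion) == 2) {
    cen <- colMeans(p)
    ang <- atan2(p[, 2] - cen[2], p[, 1] - cen[1]) * 180 / pi
    span <- (exclusion[2] - exclusion[1]) %% 360
    rel <- (ang - exclusion[1]) %% 360
    keep <- !(rel <= span)
  }
  q <- p[keep, , drop = FALSE]
  if (nrow(q) < 6) stop("too few points outside the exclusion (", nrow(q),
                        " < 6) for a circle fit")
  A <- cbind(2 * q[, 1], 2 * q[, 2], 1)
  b <- q[, 1]^2 + q[, 2]^2
  qrA <- qr(A)
  if (qrA$rank < 3) stop("collinear points: circle fit is degenerate")
  sol <- qr.coef(qrA, b)
  center <- sol[1:2]
  r2 <- sol[3] + sum(center^2)
  if (r2 <= 0) stop("collinear points: circle fit is degenerate")
  radius <- sqrt(r2)
  res <- sqrt(rowSums(sweep(q, 2, center)^2)) - radius
  list(center = as.numeric(center), radius = as.numeric(radius),
       rms_residual = sqrt(mean(res^2)))
}

contourAngles <- function(p, center) atan2(p[, 2] - center[2], p[, 1] - center[1])

# RMS Sampson (first-order geometric) distance of the contour points to
# their global least-squares conic, in mm.  A healthy quasi-elliptic head
# section is explained by a single smooth conic; a subchondral recession
# is not, so this separates "no articular alteration" from a real one
# even when the section is visibly elliptic rather than circular.
conicMisfit <- function(p) {
  cen <- colMeans(p)
  sc <- mean(sqrt(rowSums(sweep(p, 2, cen)^2)))
  x <- (p[, 1] - cen[1]) / sc
  y <- (p[, 2] - cen[2]) / sc
  D <- cbind(x^2, x * y, y^2, x, y, 1)
  a <- svd(D, nu = 0)$v[, 6]
  if (a[2]^2 - 4 * a[1] * a[3] >= 0) return(Inf) # not an ellipse
  val <- as.numeric(D %*% a)
  gx <- 2 * a[1] * x + a[2] * y + a[4]
  gy <- a[2] * x + 2 * a[3] * y + a[5]
  samp <- abs(val) / pmax(sqrt(gx^2 + gy^2), 1e-12)
  sqrt(mean(samp^2)) * sc
}

# First index (walking from `start` by `step` through the closed contour)
# whose inward radial deviation exceeds `tol` and keeps exceeding it over
# the persistence arc.  The articular alteration is always an inward
# recession (subchondral bone lies under the cartilage), so outward
# circle-fit misfit on a slightly elliptic nonarticular arc cannot
# trigger a junction.  Returns NA when no such point exists.
walkToJunction <- function(p, dev, start, step, tol, center, radius,
                           persist_rad) {
  n <- nrow(p)
  npersist <- max(1L, ceiling(persist_rad * radius /
                                mean(sqrt(rowSums((p - p[c(2:n, 1), ])^2)))))
  idx <- start
  for (moved in seq_len(n - 1L)) {
    idx <- ((idx - 1L + step) %% n) + 1L
    if (dev[idx] < -tol) {
      ahead <- ((idx - 1L + step * seq_len(npersist)) %% n) + 1L
      if (all(dev[ahead] < -tol)) return(idx)
    }
  }
  NA_integer_
}

#' Detect the articular-nonarticular junctions of a head contour
#'
#' Fits the nonarticular reference circle iteratively (first excluding the
#' half-plane facing the opposing bone, then excluding the detected
#' articular arc and refitting) and walks the contour from the nonarticular
#' side toward the articular side in both directions.  Each junction is the
#' first point whose radial deviation from the reference circle exceeds
#' `deviation_tol` (inward, the direction of a subchondral recession) and
#' stays exceeded over the persistence arc.
#'
#' @param contour a [SliceContour-class] of the radial head.
#' @param opposing_direction unit 2-D vector from the head centroid toward
#'   the opposing bone (ulna) centroid in this slice.
#' @param deviation_tol radial deviation threshold in mm.  Default
#'   `max(0.3, 1.5 * inplane_voxel)`: large enough to ride over
#'   voxelisation ripple, small enough to catch sub-millimetre cartilage.
#' @param inplane_voxel in-plane voxel edge (mm), used for the default
#'   tolerance.
#' @param persistence_deg arc (degrees) over which the deviation must
#'   persist before a point counts as a junction; suppresses isolated
#'   noise-triggered detections.
#' @return An [ANAJunctionPair-class].
#' @details Errors with "no articular alteration detected" when no point
#'   exceeds the tolerance, and with "implausible articular arc" when the
#'   detected junctions subtend an arc below 10 or above 180 degrees.
#' @export
detectAnaJunctions <- function(contour, opposing_direction,
                               deviation_tol = NULL, inplane_voxel = 0.2,
                               persistence_deg = 5) {
  p <- contour@points
  n <- nrow(p)
  od <- opposing_direction / sqrt(sum(opposing_direction^2))
  if (is.null(deviation_tol)) deviation_tol <- max(0.3, 1.5 * inplane_voxel)
  # a contour that one smooth conic explains has no articular alteration
  # (the exclusion-based circle fit below would otherwise extrapolate a
  # spurious recession across the flatter side of an elliptic section)
  if (nrow(p) >= 12 && conicMisfit(p) < deviation_tol / 4)
    stop("no articular alteration detected on the contour")
  cen0 <- colMeans(p)
  side <- as.numeric((p[, 1] - cen0[1]) * od[1] + (p[, 2] - cen0[2]) * od[2])
  excl <- side > 0
  if (sum(!excl) < 6) excl <- side > stats::quantile(side, 0.5)
  persist_rad <- persistence_deg * pi / 180
  res <- NULL
  for (round in 1:2) {
    fit <- fitReferenceCircle(p, exclusion = excl)
    dev <- sqrt(rowSums(sweep(p, 2, fit$center)^2)) - fit$radius
    start <- which.min(side)
    i1 <- walkToJunction(p, dev, start, -1L, deviation_tol,
                         fit$center, fit$radius, persist_rad)
    i2 <- walkToJunction(p, dev, start, +1L, deviation_tol,
                         fit$center, fit$radius, persist_rad)
    if (is.na(i1) || is.na(i2))
      stop("no articular alteration detected on the contour")
    res <- list(fit = fit, i1 = i1, i2 = i2)
    if (round == 1) {
      # exclude the detected articular range (plus margin) and refit
      rng <- articularIndexRange(n, i1, i2, start)
      margin <- max(2L, round(n * 0.02))
      rngm <- unique(as.vector(outer(rng - 1L, -margin:margin, `+`)) %% n + 1L)
      excl <- rep(FALSE, n)
      excl[rngm] <- TRUE
      if (sum(!excl) < 6) break
    }
  }
  fit <- res$fit; i1 <- res$i1; i2 <- res$i2
  j1 <- p[i1, ]; j2 <- p[i2, ]
  chord <- j2 - j1
  cl <- sqrt(sum(chord^2))
  if (cl < 1e-9) stop("no articular alteration detected on the contour")
  perp <- od - chord * sum(od * chord) / cl^2
  pn <- sqrt(sum(perp^2))
  aside <- if (pn > 1e-9) perp / pn else od
  a1 <- contourAngles(p[i1, , drop = FALSE], fit$center)
  a2 <- contourAngles(p[i2, , drop = FALSE], fit$center)
  amid <- atan2(aside[2], aside[1])
  # arc subtended on the articular side
  arc <- ((a2 - a1) %% (2 * pi))
  if (((amid - a1) %% (2 * pi)) > arc) arc <- 2 * pi - arc
  arc_deg <- arc * 180 / pi
  if (arc_deg < 10 || arc_deg > 180)
    stop(sprintf("implausible articular arc (%.1f deg)", arc_deg))
  new("ANAJunctionPair", j1 = as.numeric(j1), j2 = as.numeric(j2),
      articularSide = as.numeric(aside), i1 = i1, i2 = i2,
      center = fit$center, radius = fit$radius)
}

# Contour indices from i1 to i2 passing through the articular portion
# (the range NOT containing the nonarticular start point).
articularIndexRange <- function(n, i1, i2, start) {
  fwd <- if (i1 <= i2) i1:i2 else c(i1:n, 1:i2)
  if (start %in% fwd) {
    fwd <- if (i2 <= i1) i2:i1 else c(i2:n, 1:i1)
    rev(fwd)
  } else fwd
}

#' Reforming axis from a junction pair
#'
#' The perpendicular through the midpoint of the straight line between the
#' two ANA junctions, oriented toward the articular side.
#'
#' @param junctions an [ANAJunctionPair-class].
#' @param inplane_voxel degenerate-chord guard: the chord must be at least
#'   one in-plane voxel long.
#' @return A [ReformingAxis-class].
#' @export
reformingAxis <- function(junctions, inplane_voxel = 0.2) {
  chord <- junctions@j2 - junctions@j1
  cl <- sqrt(sum(chord^2))
  if (cl < inplane_voxel)
    stop("degenerate chord: junctions are less than one voxel apart")
  dir <- c(-chord[2], chord[1]) / cl
  if (sum(dir * junctions@articularSide) < 0) dir <- -dir
  new("ReformingAxis", origin = as.numeric((junctions@j1 + junctions@j2) / 2),
      direction = as.numeric(dir))
}

# Intersections of ray (origin + t * dir, t real) with a closed polygon;
# returns sorted t values of crossings.
rayPolygon <- function(poly, origin, dir) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  e <- b - a
  denom <- dir[1] * (-e[, 2]) - dir[2] * (-e[, 1])
  w <- cbind(a[, 1] - origin[1], a[, 2] - origin[2])
  t <- (w[, 1] * (-e[, 2]) - w[, 2] * (-e[, 1])) / denom
  u <- (dir[1] * w[, 2] - dir[2] * w[, 1]) / denom
  ok <- is.finite(t) & u >= 0 & u < 1
  sort(t[ok])
}

#' Measure the subchondral gap along the reforming axis
#'
#' Casts the ray of the reforming axis; the head-side point is the last
#' crossing of the head contour along the ray, the opposing point the first
#' crossing of the opposing contour beyond it.  The ray through the chord
#' midpoint operationalises the mid portion of the radial notch.
#'
#' @param head_contour,opposing_contour [SliceContour-class] objects in the
#'   same slice.
#' @param axis a [ReformingAxis-class].
#' @return A [GapMeasurement-class].
#' @export
subchondralGap <- function(head_contour, opposing_contour, axis) {
  th <- rayPolygon(head_contour@points, axis@origin, axis@direction)
  if (length(th) == 0) stop("reforming axis misses the head contour")
  t_head <- max(th)
  to <- rayPolygon(opposing_contour@points, axis@origin, axis@direction)
  to_beyond <- to[to >= t_head - 1e-9]
  if (length(to_beyond) == 0) {
    if (length(to[to > min(th)]) > 0)
      stop("overlapping masks: opposing contour crosses inside the head")
    stop("joint not apposed along axis")
  }
  t_opp <- min(to_beyond)
  ph <- axis@origin + t_head * axis@direction
  po <- axis@origin + t_opp * axis@direction
  new("GapMeasurement", gap = t_opp - t_head,
      pointOnHead = as.numeric(ph), pointOnOpposing = as.numeric(po))
}

# Sample a circular blending arc from p to q on the circle tangent to the
# reference circle at p (centre on the radial line through p).  Falls back
# to NULL (straight closure) when the geometry is degenerate.
blendArc <- function(p, q, ref_center, step_mm) {
  nrad <- p - ref_center
  nn <- sqrt(sum(nrad^2))
  if (nn < 1e-12) return(NULL)
  nrad <- nrad / nn
  dpq <- q - p
  den <- 2 * sum(dpq * nrad)
  if (abs(den) < 1e-9) return(NULL)
  s <- sum(dpq^2) / den
  cen <- p + s * nrad
  r <- abs(s)
  a1 <- atan2(p[2] - cen[2], p[1] - cen[1])
  a2 <- atan2(q[2] - cen[2], q[1] - cen[1])
  sweep <- (a2 - a1) %% (2 * pi)
  if (sweep > pi) sweep <- sweep - 2 * pi # take the short way round
  nseg <- max(2L, ceiling(abs(sweep) * r / step_mm))
  ang <- a1 + sweep * seq(0, 1, length.out = nseg + 1L)
  inner <- cbind(cen[1] + r * cos(ang), cen[2] + r * sin(ang))
  inner[-c(1, nrow(inner)), , drop = FALSE]
}

#' Reform a head contour by translating its articular portion
#'
#' Rigidly translates the articular sub-arc (between the two junctions, on
#' the articular side) by `delta` mm along the reforming axis, then closes
#' the two uneven borders over the junctions with blending arcs tangent to
#' the nonarticular reference circle, so the reformed boundary runs on the
#' same arch.  Falls back to straight closures if an arc would
#' self-intersect the contour.
#'
#' @param head_contour a [SliceContour-class].
#' @param junctions an [ANAJunctionPair-class] detected on that contour.
#' @param axis a [ReformingAxis-class].
#' @param delta translation distance (mm, `>= 0`).
#' @return A [SliceContour-class]; its enclosed area is never below the
#'   input area.
#' @export
reformSlice <- function(head_contour, junctions, axis, delta) {
  if (delta < 0) stop("delta must be >= 0")
  p <- head_contour@points
  n <- nrow(p)
  if (delta == 0) return(head_contour)
  start <- which.min((p[, 1] - mean(p[, 1])) * axis@direction[1] +
                     (p[, 2] - mean(p[, 2])) * axis@direction[2])
  art <- articularIndexRange(n, junctions@i1, junctions@i2, start)
  non <- setdiff(seq_len(n), art[-c(1, length(art))])
  # order nonarticular path from i2 around to i1
  nonpath <- articularIndexRange(n, junctions@i2, junctions@i1, art[2])
  shift <- delta * axis@direction
  artp <- sweep(p[art, , drop = FALSE], 2, -shift)
  step_mm <- mean(sqrt(rowSums((p - p[c(2:n, 1), ])^2)))
  for (use_arcs in c(TRUE, FALSE)) {
    b1 <- if (use_arcs)
      blendArc(p[art[1], ], artp[1, ], junctions@center, step_mm) else NULL
    b2 <- if (use_arcs)
      blendArc(artp[nrow(artp), ], p[art[length(art)], ],
               junctions@center, step_mm) else NULL
    out <- rbind(p[nonpath, , drop = FALSE], b1, artp, b2)
    out <- out[!duplicated(out), , drop = FALSE]
    if (!.cct_polygon_self_intersects(out)) {
      res <- SliceContour(out, z = head_contour@z,
                          boneLabel = head_contour@boneLabel)
      if (polygonArea(res@points) >= polygonArea(p) - 1e-9) return(res)
    }
  }
  stop("reform produced invalid contour")
}
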