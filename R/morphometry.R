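# Radial-head morphometry: articular rim, rim best-fit plane, disc centre,
# reference frame fixed on the gold-standard model, and the five Table-style
# parameters (coronal/sagittal diameter, medial/lateral rim thickness,
# articular disc depth).

# Plane cross-section of a mesh: returns a 2m x 3 matrix of segment
# endpoints (rows 2i-1, 2i bound one segment).
meshSection <- function(mesh, point, normal) {
  n <- normal / sqrt(sum(normal^2))
  v <- mesh@vertices
  f <- mesh@faces
  d <- as.numeric(v %*% n) - sum(point * n)
  d[abs(d) < 1e-12] <- 1e-12 # nudge on-plane vertices off the plane
  da <- d[f[, 1]]; db <- d[f[, 2]]; dc <- d[f[, 3]]
  cross_face <- !(sign(da) == sign(db) & sign(db) == sign(dc))
  if (!any(cross_face)) return(matrix(0, 0, 3))
  fa <- f[cross_face, , drop = FALSE]
  segs <- matrix(0, 2 * nrow(fa), 3)
  edgeHit <- function(i1, i2) {
    d1 <- d[i1]; d2 <- d[i2]
    hit <- sign(d1) != sign(d2)
    t <- d1 / (d1 - d2)
    list(hit = hit, pts = v[i1, , drop = FALSE] +
           (v[i2, , drop = FALSE] - v[i1, , drop = FALSE]) * t)
  }
  e1 <- edgeHit(fa[, 1], fa[, 2])
  e2 <- edgeHit(fa[, 2], fa[, 3])
  e3 <- edgeHit(fa[, 3], fa[, 1])
  for (r in seq_len(nrow(fa))) {
    pts <- rbind(if (e1$hit[r]) e1$pts[r, ],
                 if (e2$hit[r]) e2$pts[r, ],
                 if (e3$hit[r]) e3$pts[r, ])
    segs[(2 * r - 1):(2 * r), ] <- pts[1:2, ]
  }
  segs
}

# Chord of a mesh cross-section along the in-plane line through `axis_point`
# with direction `dir` (both in the section plane with normal `normal`).
sectionChord <- function(mesh, level_point, normal, axis_point, dir) {
  segs <- meshSection(mesh, level_point, normal)
  if (nrow(segs) == 0) stop("empty cross-section")
  e <- pracmaCross(normal, dir)
  eta <- as.numeric(sweep(segs, 2, axis_point) %*% e)
  xi <- as.numeric(sweep(segs, 2, axis_point) %*% dir)
  i1 <- seq(1, nrow(segs), 2)
  h1 <- eta[i1]; h2 <- eta[i1 + 1]
  crossing <- sign(h1) != sign(h2) & abs(h1 - h2) > 1e-14
  if (!any(crossing)) stop("section does not cross the measurement line")
  t <- h1[crossing] / (h1[crossing] - h2[crossing])
  xs <- xi[i1][crossing] + t * (xi[i1 + 1][crossing] - xi[i1][crossing])
  max(xs) - min(xs)
}

pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Extract the articular rim loop
#'
#' Bins the surface into 360 one-degree azimuth sectors around the head
#' axis and keeps, per sector, the most proximal surface point (largest
#' coordinate along `axial_normal`; radial ties go to the outer point).
#'
#' @param mesh a watertight [TriMesh-class] of the proximal radius.
#' @param axial_normal unit vector pointing proximally (out of the dish).
#' @param center optional axis anchor (mm); default the vertex centroid.
#' @param nbins number of azimuth bins.
#' @return `k x 3` matrix of rim points ordered by azimuth (`k <= nbins`).
#'   A degenerate-rim warning is raised when the rim radius collapses
#'   (e.g. a sphere, which has no dish).
#' @export
articularRim <- function(mesh, axial_normal, center = NULL, nbins = 360) {
  a <- axial_normal / sqrt(sum(axial_normal^2))
  v <- mesh@vertices
  if (is.null(center)) center <- colMeans(v)
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - a * sum(ref * a); u <- u / sqrt(sum(u^2))
  w <- pracmaCross(a, u)
  rel <- sweep(v, 2, center)
  x <- as.numeric(rel %*% u); y <- as.numeric(rel %*% w)
  h <- as.numeric(rel %*% a)
  r <- sqrt(x^2 + y^2)
  az <- (atan2(y, x) %% (2 * pi))
  bin <- pmin(nbins, floor(az / (2 * pi) * nbins) + 1L)
  ord <- order(bin, h, r) # last element per bin = max h, ties to outer r
  last <- ord[!duplicated(bin[ord], fromLast = TRUE)]
  last <- last[order(bin[last])]
  rim <- v[last, , drop = FALSE]
  rim_r <- r[last]
  if (stats::median(rim_r) < 0.6 * max(r))
    warning("degenerate rim: no proximal rim structure (flat or convex surface)")
  rim
}

#' Total-least-squares plane through points
#'
#' @param points `n x 3` matrix (`n >= 3`, not collinear).
#' @param orient optional vector; the normal is flipped to have a positive
#'   dot product with it (used to keep rim-plane normals proximal).
#' @return list with `point` (centroid) and `normal` (unit).
#' @export
bestFitPlane <- function(points, orient = c(0, 0, 1)) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points for a plane")
  cen <- colMeans(points)
  sv <- svd(sweep(points, 2, cen))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("collinear points: plane fit is degenerate")
  n <- sv$v[, 3]
  if (sum(n * orient) < 0) n <- -n
  list(point = as.numeric(cen), normal = as.numeric(n))
}

#' Centre of the articular disc
#'
#' The articular-surface point with maximal distance below the best-fit rim
#' plane; exact ties are resolved by the centroid of the tied set.
#' Candidate points are restricted to the dish: radially inside the rim and
#' within half a rim-radius below the plane (so the diaphysis, which is
#' also below the rim plane, cannot win).
#'
#' @param mesh a [TriMesh-class].
#' @param rim_plane list with `point`/`normal` from [bestFitPlane()]
#'   (normal proximal).
#' @param rim optional rim loop from [articularRim()]; recomputed if NULL.
#' @return length-3 point (mm).
#' @export
discCenter <- function(mesh, rim_plane, rim = NULL) {
  n <- rim_plane$normal / sqrt(sum(rim_plane$normal^2))
  if (is.null(rim)) rim <- articularRim(mesh, n)
  v <- mesh@vertices
  sd <- as.numeric(sweep(v, 2, rim_plane$point) %*% n) # positive above plane
  rim_cen <- colMeans(rim)
  relr <- sweep(rim, 2, rim_cen); relr <- relr - outer(as.numeric(relr %*% n), n)
  rim_radius <- sqrt(rowSums(relr^2))
  relv <- sweep(v, 2, rim_cen); relv <- relv - outer(as.numeric(relv %*% n), n)
  vr <- sqrt(rowSums(relv^2))
  cap <- 0.6 * stats::median(rim_radius)
  cand <- sd <= 1e-6 & -sd <= cap & vr <= 0.98 * stats::median(rim_radius)
  if (!any(cand)) stop("no articular surface point below the rim plane")
  depth <- -sd
  dmax <- max(depth[cand])
  tied <- cand & depth >= dmax - 1e-9
  as.numeric(colMeans(v[tied, , drop = FALSE]))
}

#' Head-neck junction vertex of a profile curve
#'
#' The point of the curve farthest from the straight line between its first
#' and last points (the standard rule for locating the head-neck junction
#' on a profile); ties go to the first point along the curve.
#'
#' @param profile ordered `n x 2` (or `n x 3`) curve with distinct
#'   endpoints, `n >= 3`.
#' @return The vertex as a point of the same dimension.
#' @export
headneckVertex <- function(profile) {
  p <- as.matrix(profile)
  if (nrow(p) < 3) stop("profile needs at least 3 points")
  a <- p[1, ]; b <- p[nrow(p), ]
  ab <- b - a
  L <- sqrt(sum(ab^2))
  if (L < 1e-12) stop("profile endpoints coincide")
  rel <- sweep(p, 2, a)
  proj <- (rel %*% ab) / L
  d <- sqrt(pmax(0, rowSums(rel^2) - as.numeric(proj)^2))
  if (max(d) < 1e-6) stop("no vertex: profile is a straight segment")
  as.numeric(p[which.max(d), ])
}

# Outer-boundary profile of the coronal section on one side (sign = +1
# toward the tuberosity / lateral, -1 toward the ulna / medial), as an
# ordered (|s|, h) curve from the narrowest neck level up to the rim.
coronalSideProfile <- function(segs, u, axial, center, side_sign,
                               hbin = 0.35) {
  rel <- sweep(segs, 2, center)
  s <- as.numeric(rel %*% u)
  h <- as.numeric(rel %*% axial)
  keep <- side_sign * s > 0
  s <- abs(s[keep]); h <- h[keep]
  if (length(s) < 3) stop("coronal section side is empty")
  bins <- round(h / hbin)
  smax <- tapply(s, bins, max)
  hb <- as.numeric(names(smax)) * hbin
  ord <- order(hb)
  smax <- as.numeric(smax)[ord]; hb <- hb[ord]
  i_wide <- which.max(smax)
  # narrowest neck level bounding the head-neck transition: walk distally
  # from the widest level while the radius keeps shrinking (a small slack
  # rides over surface ripple); the tuberosity widens the shaft again
  # further down, so the first local minimum is the neck waist
  i_narrow <- i_wide
  while (i_narrow > 1 && smax[i_narrow - 1] < smax[i_narrow] - 0.02)
    i_narrow <- i_narrow - 1L
  list(curve = cbind(smax[i_narrow:length(smax)], hb[i_narrow:length(smax)]),
       side_sign = side_sign)
}

#' Build the measurement reference frame from the gold-standard model
#'
#' The axial normal is the rim-plane normal; the coronal plane contains the
#' disc centre and the tuberosity direction (projected orthogonal to the
#' axial normal); the sagittal normal completes the right-handed triad.
#' The axial measurement level is the level with the longest coronal
#' diameter on the gold model, and the head-neck junction line connects
#' the junction vertices found on the medial and lateral coronal profiles.
#'
#' @param mesh_gold gold-standard [TriMesh-class].
#' @param tuberosity_point landmark (mm) at the middle of the radial
#'   tuberosity; must lie within 1 mm of the surface.
#' @param axial_hint rough proximal direction used to seed rim extraction.
#' @return A [ReferenceFrame-class].
#' @export
referenceFrame <- function(mesh_gold, tuberosity_point,
                           axial_hint = c(0, 0, 1)) {
  nd <- .cct_nearest_on_surface(matrix(tuberosity_point, 1, 3),
                                mesh_gold@vertices, mesh_gold@faces)$distance
  if (nd > 1) stop("tuberosity point is ", round(nd, 2),
                   " mm off the surface (max 1 mm)")
  a <- axial_hint / sqrt(sum(axial_hint^2))
  for (it in 1:2) { # rim and plane refine each other once
    rim <- articularRim(mesh_gold, a)
    pl <- bestFitPlane(rim, orient = a)
    a <- pl$normal
  }
  dc <- discCenter(mesh_gold, pl, rim = rim)
  tdir <- tuberosity_point - dc
  tproj <- tdir - a * sum(tdir * a)
  tn <- sqrt(sum(tproj^2))
  if (tn < 1e-6)
    stop("tuberosity direction is parallel to the axial normal")
  u <- tproj / tn # unit, disc centre -> tuberosity (lateral side)
  cn <- pracmaCross(u, a)
  sn <- u # right-handed: cn x sn = a
  segs <- meshSection(mesh_gold, dc, cn)
  vtx <- lapply(c(-1, 1), function(sg) {
    pr <- coronalSideProfile(segs, u, a, dc, sg)
    v2 <- headneckVertex(pr$curve)
    dc + sg * v2[1] * u + v2[2] * a
  })
  jdir <- vtx[[2]] - vtx[[1]]
  jline <- list(point = as.numeric(vtx[[1]]),
                direction = as.numeric(jdir / sqrt(sum(jdir^2))))
  # axial level with the longest coronal diameter, searched between the
  # junction and the rim plane
  h_rim <- sum(colMeans(rim) * a)
  h_junction <- max(sum(vtx[[1]] * a), sum(vtx[[2]] * a))
  hs <- seq(h_junction + 0.25, h_rim - 0.25, by = 0.25)
  axp <- dc - a * sum(dc * a) # in-plane part of the disc-centre axis
  chord <- vapply(hs, function(h) {
    tryCatch(sectionChord(mesh_gold, axp + h * a, a, axp + h * a, u),
             error = function(e) NA_real_)
  }, 0)
  if (all(is.na(chord))) stop("no usable axial level between junction and rim")
  best <- which(chord >= max(chord, na.rm = TRUE) - 1e-6)
  lvl <- hs[round(stats::median(best))]
  new("ReferenceFrame", discCenter = as.numeric(dc),
      coronalNormal = as.numeric(cn), sagittalNormal = as.numeric(sn),
      axialNormal = as.numeric(a), axialLevel = lvl, junctionLine = jline)
}

#' Head diameters at the reference axial level
#'
#' Chords of the axial cross-section taken through the disc-centre axis:
#' the coronal diameter along the coronal plane's in-plane direction (the
#' disc-centre-to-tuberosity line) and the sagittal diameter along the
#' perpendicular in-plane direction.
#'
#' @param mesh a [TriMesh-class] (any of the three models).
#' @param frame the gold-standard [ReferenceFrame-class].
#' @return named numeric `c(coronal, sagittal)` in mm.
#' @export
headDiameters <- function(mesh, frame) {
  a <- frame@axialNormal
  axp <- frame@discCenter - a * sum(frame@discCenter * a) + frame@axialLevel * a
  cor <- sectionChord(mesh, axp, a, axp, frame@sagittalNormal)
  sag <- sectionChord(mesh, axp, a, axp, frame@coronalNormal)
  c(coronal = cor, sagittal = sag)
}

# Most proximal point of the coronal section on one side, as (s, h).
proximalRimPoint <- function(segs, u, axial, center, side_sign) {
  rel <- sweep(segs, 2, center)
  s <- as.numeric(rel %*% u)
  h <- as.numeric(rel %*% axial)
  keep <- side_sign * s > 0.05
  if (!any(keep)) stop("coronal section side is empty")
  i <- which(keep)[which.max(h[keep])]
  c(s = s[i], h = h[i])
}

#' Medial and lateral rim thickness
#'
#' In the coronal section, the distance parallel to the axial normal from
#' the head-neck junction line to the most proximal point of each rim.
#' Medial is the side toward the ulna (away from the tuberosity), lateral
#' the tuberosity side.
#'
#' @param mesh a [TriMesh-class].
#' @param frame gold-standard [ReferenceFrame-class] (its junction line is
#'   used for every model of the specimen).
#' @return named numeric `c(medial, lateral)` in mm.
#' @export
rimThickness <- function(mesh, frame) {
  if (length(frame@junctionLine) == 0)
    stop("reference frame has no junction line")
  a <- frame@axialNormal; u <- frame@sagittalNormal
  segs <- meshSection(mesh, frame@discCenter, frame@coronalNormal)
  if (nrow(segs) == 0) stop("empty coronal section")
  jp <- frame@junctionLine$point; jd <- frame@junctionLine$direction
  lineH <- function(s_target) {
    # junction-line height at in-plane coordinate s (parallel-to-axial rule)
    s0 <- sum((jp - frame@discCenter) * u)
    ds <- sum(jd * u)
    h0 <- sum((jp - frame@discCenter) * a)
    dh <- sum(jd * a)
    if (abs(ds) < 1e-9) h0 else h0 + (s_target - s0) / ds * dh
  }
  med <- proximalRimPoint(segs, u, a, frame@discCenter, -1)
  lat <- proximalRimPoint(segs, u, a, frame@discCenter, +1)
  c(medial = unname(med["h"] - lineH(med["s"])),
    lateral = unname(lat["h"] - lineH(lat["s"])))
}

#' Articular disc depth
#'
#' In the coronal section, the perpendicular distance from the deepest
#' articular point to the line between the most proximal medial and
#' lateral rim points.
#'
#' @param mesh a [TriMesh-class].
#' @param frame gold-standard [ReferenceFrame-class].
#' @return depth in mm (0 for a flat-topped solid).
#' @export
discDepth <- function(mesh, frame) {
  a <- frame@axialNormal; u <- frame@sagittalNormal
  segs <- meshSection(mesh, frame@discCenter, frame@coronalNormal)
  if (nrow(segs) == 0) stop("empty coronal section")
  med <- proximalRimPoint(segs, u, a, frame@discCenter, -1)
  lat <- proximalRimPoint(segs, u, a, frame@discCenter, +1)
  rel <- sweep(segs, 2, frame@discCenter)
  s <- as.numeric(rel %*% u); h <- as.numeric(rel %*% a)
  # the articular dish is the upper envelope of the section between the
  # rims: per s-bin keep the most proximal point, so the head under-face
  # and the shaft outline (also between the rims, but deep below) can
  # never masquerade as the articular surface
  span <- abs(lat["s"] - med["s"])
  inb <- s > min(med["s"], lat["s"]) + 0.02 * span &
         s < max(med["s"], lat["s"]) - 0.02 * span
  if (!any(inb)) return(0)
  si <- s[inb]; hi <- h[inb]
  bin <- round(si / 0.3)
  top_idx <- vapply(split(seq_along(hi), bin),
                    function(ix) ix[which.max(hi[ix])], 0L)
  sb <- si[top_idx]; hb <- hi[top_idx]
  # perpendicular distance below the inter-rim line
  ldir <- c(lat["s"] - med["s"], lat["h"] - med["h"])
  ldir <- ldir / sqrt(sum(ldir^2))
  below <- -((sb - med["s"]) * (-ldir[2]) + (hb - med["h"]) * ldir[1])
  max(0, max(below))
}

#' Measure the five radial-head parameters
#'
#' @param mesh the model under test (a [TriMesh-class]).
#' @param frame the gold-standard [ReferenceFrame-class] of the same
#'   specimen.
#' @return A [MorphometricReport-class].  Errors from individual
#'   measurements are re-raised with the parameter name; a frame whose disc
#'   centre is far off this mesh's surface triggers a scale/specimen
#'   mismatch warning.
#' @export
measureAll <- function(mesh, frame) {
  nd <- .cct_nearest_on_surface(matrix(frame@discCenter, 1, 3),
                                mesh@vertices, mesh@faces)$distance
  if (nd > 5)
    warning("frame disc centre is ", round(nd, 1),
            " mm off this mesh: frame may belong to a different specimen")
  wrap <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE))
  dia <- wrap("diameters", headDiameters(mesh, frame))
  th <- wrap("rim thickness", rimThickness(mesh, frame))
  dep <- wrap("disc depth", discDepth(mesh, frame))
  suppressWarnings(MorphometricReport(
    coronalDiameter = unname(dia["coronal"]),
    sagittalDiameter = unname(dia["sagittal"]),
    medialThickness = unname(th["medial"]),
    lateralThickness = unname(th["lateral"]),
    discDepth = unname(dep)))
}
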