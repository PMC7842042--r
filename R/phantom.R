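# Synthetic elbow phantom: analytic proximal radius (elliptic head with a
# spherical articular dish and circumferential rim, neck/shaft with a
# tuberosity bump), apposed ulnar radial notch and capitellum, and
# cartilage shells of configurable thickness.  Supplies the gold-standard
# bone+cartilage geometry that CT arthrography provides in vivo.
#
# Conventions: head axis = +z (proximal), ulna faces azimuth 0 (+x),
# tuberosity azimuth 180 (-x).  The subchondral bone of the cartilage-
# covered articular sector is recessed by the cartilage thickness below
# the smooth outer envelope, so the bone-only contour shows the
# characteristic alteration of the circular nonarticular curve.

#' PhantomSpec: parameters of one synthetic elbow
#'
#' All lengths in mm, HU for intensities.  The articular (cartilage
#' covered) sector of the rim wall spans `articularSectorDeg` of azimuth
#' facing the ulnar notch; the dish and rim crest are cartilage covered on
#' the full circumference.
#'
#' @slot headCoronalRadius,headSagittalRadius subchondral semi-axes of the
#'   articular head section (the outer bone+cartilage envelope adds
#'   `rimCartilageT`).
#' @slot headHeight envelope head height above the head-neck junction.
#' @slot dishSphereRadius,dishDepth radius of curvature and sagitta of the
#'   articular dish (`dishDepth <= dishSphereRadius`).
#' @slot neckRadius,shaftLength neck/shaft cylinder below the junction.
#' @slot tuberosityAzimuthDeg,tuberosityHeight radial tuberosity bump.
#' @slot rimCartilageT,dishCartilageT,notchCartilageT,capitellumCartilageT
#'   cartilage thicknesses, each within 0-3.5.
#' @slot capitellumRadius capitellar sphere radius.
#' @slot fluidGap joint-space fluid thickness between apposed cartilage
#'   surfaces.
#' @slot articularSectorDeg length-2 azimuth range (deg) of the recessed
#'   articular wall sector.
#' @slot notchHalfAngleDeg,ulnaThickness ulnar notch wedge geometry.
#' @slot huBone,huCartilage,huSoft,noiseSd intensity model (HU); bone must
#'   fall inside the 250-2500 segmentation window, cartilage and soft
#'   tissue below it.
#' @slot spacing voxel spacing (mm).
#' @slot seed integer RNG seed for the additive noise.
#' @aliases PhantomSpec
#' @export
setClass("PhantomSpec",
  representation(headCoronalRadius = "numeric", headSagittalRadius = "numeric",
                 headHeight = "numeric", dishSphereRadius = "numeric",
                 dishDepth = "numeric", neckRadius = "numeric",
                 shaftLength = "numeric", tuberosityAzimuthDeg = "numeric",
                 tuberosityHeight = "numeric", rimCartilageT = "numeric",
                 dishCartilageT = "numeric", notchCartilageT = "numeric",
                 capitellumCartilageT = "numeric", capitellumRadius = "numeric",
                 fluidGap = "numeric", articularSectorDeg = "numeric",
                 notchHalfAngleDeg = "numeric", ulnaThickness = "numeric",
                 huBone = "numeric", huCartilage = "numeric",
                 huSoft = "numeric", noiseSd = "numeric",
                 spacing = "numeric", seed = "integer"),
  validity = function(object) {
    lens <- c(object@headCoronalRadius, object@headSagittalRadius,
              object@headHeight, object@dishSphereRadius, object@dishDepth,
              object@neckRadius, object@shaftLength, object@tuberosityHeight,
              object@capitellumRadius, object@fluidGap, object@ulnaThickness)
    if (any(lens < 0)) return("all lengths must be >= 0")
    carts <- c(object@rimCartilageT, object@dishCartilageT,
               object@notchCartilageT, object@capitellumCartilageT)
    if (any(carts < 0) || any(carts > 3.5))
      return("cartilage thicknesses must lie in [0, 3.5] mm")
    if (object@dishDepth > object@dishSphereRadius)
      return("dishDepth must not exceed dishSphereRadius")
    if (object@huBone < 250 || object@huBone > 2500)
      return("huBone must lie inside the 250-2500 segmentation window")
    if (object@huCartilage >= 250 || object@huSoft >= 250)
      return("huCartilage and huSoft must stay below the 250 HU threshold")
    if (length(object@spacing) != 3 || any(object@spacing <= 0))
      return("spacing must be 3 positive numbers")
    TRUE
  })

#' Construct a PhantomSpec
#'
#' Defaults reproduce one plausible cadaveric proximal radius scanned at
#' 0.2 x 0.2 x 0.3 mm: subchondral coronal semi-axis 9.9 mm (gold coronal
#' diameter 21.8 mm with 1 mm rim cartilage), dish depth 2 mm, uniform
#' 1 mm cartilage, apposed joints without free fluid.
#'
#' @param ... slot overrides, see [PhantomSpec-class].
#' @return A validated [PhantomSpec-class].
#' @export
phantomSpec <- function(...) {
  defaults <- list(headCoronalRadius = 9.9, headSagittalRadius = 10.2,
                   headHeight = 10.5, dishSphereRadius = 24, dishDepth = 2,
                   neckRadius = 7.5, shaftLength = 12,
                   tuberosityAzimuthDeg = 180, tuberosityHeight = 1.8,
                   rimCartilageT = 1, dishCartilageT = 1,
                   notchCartilageT = 1, capitellumCartilageT = 1,
                   capitellumRadius = 12, fluidGap = 0,
                   articularSectorDeg = c(-55, 115),
                   notchHalfAngleDeg = 45, ulnaThickness = 8,
                   huBone = 700, huCartilage = 80, huSoft = 30,
                   noiseSd = 10, spacing = c(0.2, 0.2, 0.3), seed = 1L)
  args <- list(...)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown)) stop("unknown phantom fields: ",
                            paste(unknown, collapse = ", "))
  defaults[names(args)] <- args
  defaults$seed <- as.integer(defaults$seed)
  do.call(new, c(list("PhantomSpec"), defaults))
}

# Derived geometry shared by rasterisation, truth meshes and closed forms.
# The rim crest carries cartilage of the rim thickness, the dish cartilage
# of the (usually thinner) dish thickness; the envelope dish is the sphere
# through the crest circle with its pole dishCartilageT above the bone
# pole, so the gold disc depth is dishDepth + rimCartilageT -
# dishCartilageT (the mechanism by which plain CT underestimates depth).
phantomGeometry <- function(spec) {
  A <- spec@headCoronalRadius + spec@rimCartilageT
  B <- spec@headSagittalRadius + spec@rimCartilageT
  z0h <- spec@shaftLength               # head-neck junction level
  Zt <- z0h + spec@headHeight           # envelope rim crest level
  Zb <- Zt - spec@rimCartilageT         # bone crest level
  poleBone <- Zb - spec@dishDepth
  poleEnv <- poleBone + spec@dishCartilageT
  depthEnv <- Zt - poleEnv              # gold disc depth
  rs <- spec@dishSphereRadius
  apb <- sqrt(rs^2 - (rs - spec@dishDepth)^2) # bone dish aperture radius
  if (depthEnv <= 0)
    stop("dishCartilageT must stay below dishDepth + rimCartilageT ",
         "(the cartilage would overfill the dish)")
  rgEnv <- (apb^2 + depthEnv^2) / (2 * depthEnv) # envelope dish radius
  notchR <- A + spec@fluidGap           # ulnar cartilage facing surface
  ulnaBoneR <- notchR + spec@notchCartilageT
  zcap <- poleEnv + spec@fluidGap + spec@capitellumCartilageT +
    spec@capitellumRadius               # capitellar sphere centre height
  list(A = A, B = B, z0h = z0h, Zt = Zt, Zb = Zb, poleEnv = poleEnv,
       depthEnv = depthEnv, apb = apb, rgEnv = rgEnv,
       poleBone = poleBone,
       notchR = notchR, ulnaBoneR = ulnaBoneR, zcap = zcap,
       ztub = z0h / 2,
       # volume extents with a 1.5 mm margin
       xlim = c(-(spec@neckRadius + spec@tuberosityHeight + 2.5),
                ulnaBoneR + spec@ulnaThickness + 1.5),
       ylim = c(-1, 1) * (max(B, spec@capitellumRadius,
                              (ulnaBoneR + spec@ulnaThickness) *
                                sin(spec@notchHalfAngleDeg * pi / 180)) + 1.5),
       zlim = c(-0.9, zcap - 0.55 * spec@capitellumRadius))
}

inAzimuthSector <- function(azDeg, sector) {
  span <- (sector[2] - sector[1]) %% 360
  ((azDeg - sector[1]) %% 360) <= span
}

# Occupancy of one axial plane at height z, as logical matrices over the
# in-plane grid.  `solids`: radius bone, radius envelope (bone+cartilage),
# ulna bone, ulna cartilage, capitellum bone, capitellum cartilage.
phantomPlane <- function(spec, g, xg, yg, z) {
  nx <- length(xg); ny <- length(yg)
  X <- matrix(xg, nx, ny)
  Y <- matrix(yg, nx, ny, byrow = TRUE)
  rho2 <- X^2 + Y^2
  az <- (atan2(Y, X) * 180 / pi) %% 360
  art <- inAzimuthSector(az, spec@articularSectorDeg)
  FALSEm <- matrix(FALSE, nx, ny)
  rb <- env <- ub <- uc <- cb <- ccart <- FALSEm
  a <- spec@headCoronalRadius; b <- spec@headSagittalRadius
  if (z <= g$z0h) {
    bump <- spec@tuberosityHeight *
      exp(-((z - g$ztub) / 2.5)^2) *
      pmax(0, cos(pmin(pi / 2, abs(((az - spec@tuberosityAzimuthDeg + 180) %%
                                      360) - 180) * pi / 180 / (80 / 90))))^2
    rb <- env <- rho2 <= (spec@neckRadius + bump)^2
  } else if (z <= g$Zt) {
    eEnv <- (X / g$A)^2 + (Y / g$B)^2 <= 1
    eBone <- ifelse(art, (X / a)^2 + (Y / b)^2 <= 1, eEnv)
    zcEnv <- g$poleEnv + g$rgEnv
    dishEnv <- rho2 + (z - zcEnv)^2 <= g$rgEnv^2
    env <- eEnv & !dishEnv
    if (z <= g$Zb) {
      zcB <- g$poleBone + spec@dishSphereRadius
      dishB <- rho2 + (z - zcB)^2 <= spec@dishSphereRadius^2
      rb <- eBone & !dishB
    }
  }
  if (z >= g$z0h - 2 && z <= g$Zt) {
    wedge <- abs(((az - 0 + 180) %% 360) - 180) <= spec@notchHalfAngleDeg
    ub <- wedge & rho2 >= g$ulnaBoneR^2 &
      rho2 <= (g$ulnaBoneR + spec@ulnaThickness)^2
    uc <- wedge & rho2 >= g$notchR^2 & rho2 < g$ulnaBoneR^2
  }
  dz2 <- (z - g$zcap)^2
  rc <- spec@capitellumRadius
  if (dz2 <= (rc + spec@capitellumCartilageT)^2) {
    s2 <- rho2 + dz2
    cb <- s2 <= rc^2
    ccart <- s2 <= (rc + spec@capitellumCartilageT)^2 & !cb
  }
  list(radius_bone = rb, radius_env = env, ulna_bone = ub,
       ulna_cart = uc, cap_bone = cb, cap_cart = ccart)
}

phantomGrid <- function(spec, g) {
  sp <- spec@spacing
  list(xg = seq(g$xlim[1], g$xlim[2], by = sp[1]),
       yg = seq(g$ylim[1], g$ylim[2], by = sp[2]),
       zg = seq(g$zlim[1], g$zlim[2], by = sp[3]))
}

#' Rasterise a phantom into a CT volume
#'
#' Voxels take `huBone` inside the bone solids (radius with recessed
#' articular subchondral surfaces, ulna, capitellum), `huCartilage` inside
#' the cartilage shells, `huSoft` elsewhere, plus Gaussian noise of sd
#' `noiseSd` drawn from the spec's seed (identical volumes for identical
#' spec and seed; the caller's RNG state is preserved).
#'
#' @param spec a [PhantomSpec-class].
#' @return A [CTVolume-class].
#' @export
rasterizePhantom <- function(spec) {
  g <- phantomGeometry(spec)
  gr <- phantomGrid(spec, g)
  nx <- length(gr$xg); ny <- length(gr$yg); nz <- length(gr$zg)
  if (nx < 8 || ny < 8 || nz < 8)
    stop("volume too small to contain the phantom solids")
  hu <- array(spec@huSoft, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    pl <- phantomPlane(spec, g, gr$xg, gr$yg, gr$zg[k])
    sl <- matrix(spec@huSoft, nx, ny)
    cart <- (pl$radius_env & !pl$radius_bone) | pl$ulna_cart | pl$cap_cart
    sl[cart] <- spec@huCartilage
    sl[pl$radius_bone | pl$ulna_bone | pl$cap_bone] <- spec@huBone
    hu[, , k] <- sl
  }
  if (spec@noiseSd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(spec@seed)
    hu <- hu + array(rnorm(length(hu), 0, spec@noiseSd), dim(hu))
  }
  CTVolume(hu, spacing = spec@spacing,
           origin = c(gr$xg[1], gr$yg[1], gr$zg[1]))
}

# Tuberosity bump height at (azimuth deg, z); matches phantomPlane.
tuberosityBump <- function(spec, azDeg, z, ztub) {
  spec@tuberosityHeight * exp(-((z - ztub) / 2.5)^2) *
    pmax(0, cos(pmin(pi / 2,
      abs(((azDeg - spec@tuberosityAzimuthDeg + 180) %% 360) - 180) *
        pi / 180 / (80 / 90))))^2
}

# Exact triangulation of the bone+cartilage envelope of the proximal
# radius.  The envelope is a single stack of closed rings (floor cap,
# shaft with tuberosity bump, head under-face, wall, rim crest, dish,
# dish pole), so a structured ring-to-ring triangulation is watertight
# and analytically exact.
analyticEnvelopeMesh <- function(spec, nphi = 720) {
  g <- phantomGeometry(spec)
  phi <- (seq_len(nphi) - 1) / nphi * 2 * pi
  azd <- phi * 180 / pi
  cphi <- cos(phi); sphi <- sin(phi)
  Re <- 1 / sqrt((cphi / g$A)^2 + (sphi / g$B)^2) # envelope ellipse radius
  rs <- g$rgEnv
  rho_ap <- g$apb                                 # dish aperture radius
  if (rho_ap >= min(Re) - 0.2)
    stop("dish aperture reaches the head wall; shrink dishSphereRadius or dishDepth")
  zc <- g$poleEnv + rs
  zfloor <- g$zlim[1] + 0.5 * spec@spacing[3]
  rings <- list()
  addRing <- function(r, z) rings[[length(rings) + 1L]] <<-
    cbind(r * cphi, r * sphi, z)
  for (z in seq(zfloor, g$z0h, by = 0.25))
    addRing(spec@neckRadius + tuberosityBump(spec, azd, z, g$ztub), z)
  rneck_top <- spec@neckRadius + tuberosityBump(spec, azd, g$z0h, g$ztub)
  for (s in seq(0, 1, length.out = 14)[-1])
    addRing(rneck_top + s * (Re - rneck_top), g$z0h)
  for (z in seq(g$z0h + 0.2, g$Zt, by = 0.2)) addRing(Re, z)
  for (s in seq(0, 1, length.out = 8)[-1])
    addRing(Re + s * (rho_ap - Re), g$Zt)
  for (r in seq(rho_ap, 0.2, length.out = 48)[-1])
    addRing(rep(r, nphi), zc - sqrt(rs^2 - r^2))
  nr <- length(rings)
  verts <- do.call(rbind, rings)
  vfloor <- nrow(verts) + 1L
  vpole <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, zfloor), c(0, 0, g$poleEnv))
  idx <- function(ring, j) (ring - 1L) * nphi + ((j - 1L) %% nphi) + 1L
  faces <- vector("list", nr + 1L)
  j <- seq_len(nphi)
  for (r in seq_len(nr - 1L)) {
    a <- idx(r, j); b <- idx(r, j + 1L)
    cta <- idx(r + 1L, j); ctb <- idx(r + 1L, j + 1L)
    faces[[r]] <- rbind(cbind(a, b, ctb), cbind(a, ctb, cta))
  }
  faces[[nr]] <- cbind(idx(1L, j + 1L), idx(1L, j), vfloor)
  faces[[nr + 1L]] <- cbind(idx(nr, j), idx(nr, j + 1L), vpole)
  TriMesh(verts, do.call(rbind, faces))
}

#' Ground-truth meshes, report and landmarks of a phantom
#'
#' The gold-standard bone+cartilage surface (`cartilage_mesh`) is an exact
#' analytic triangulation of the envelope solid; the bone-only surface
#' (`bone_mesh`) samples the analytic bone solid on the spec's voxel grid
#' (no noise, no threshold error) because its recessed articular sector
#' has azimuthal steps that the voxel grid represents naturally.  The
#' truth report comes from the closed-form geometry, not from the meshes.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `bone_mesh`, `cartilage_mesh` ([TriMesh-class]),
#'   `truth_report` (a [MorphometricReport-class]) and `truth_landmarks`
#'   (disc centre, tuberosity point, junction line, rim level, head-neck
#'   junction height, seed points).
#' @details Closed forms: coronal diameter `2 * (headCoronalRadius +
#'   rimCartilageT)`, sagittal diameter likewise from the sagittal radius,
#'   both rim thicknesses `headHeight`, disc depth
#'   `dishDepth + rimCartilageT - dishCartilageT` (rim cartilage deepens
#'   the dish, dish cartilage fills it; they cancel when equal).
#' @export
buildTruth <- function(spec) {
  g <- phantomGeometry(spec)
  gr <- phantomGrid(spec, g)
  nx <- length(gr$xg); ny <- length(gr$yg); nz <- length(gr$zg)
  bone <- array(FALSE, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    pl <- phantomPlane(spec, g, gr$xg, gr$yg, gr$zg[k])
    bone[, , k] <- pl$radius_bone
  }
  org <- c(gr$xg[1], gr$yg[1], gr$zg[1])
  bm <- meshFromMask(BinaryMask(bone, spec@spacing, org))
  cm <- analyticEnvelopeMesh(spec)
  azt <- spec@tuberosityAzimuthDeg * pi / 180
  rtub <- spec@neckRadius + spec@tuberosityHeight
  report <- suppressWarnings(MorphometricReport(
    coronalDiameter = 2 * g$A,
    sagittalDiameter = 2 * g$B,
    medialThickness = spec@headHeight,
    lateralThickness = spec@headHeight,
    discDepth = g$depthEnv))
  list(bone_mesh = bm, cartilage_mesh = cm, truth_report = report,
       truth_landmarks = list(
         disc_center = c(0, 0, g$poleEnv),
         tuberosity_point = c(rtub * cos(azt), rtub * sin(azt), g$ztub),
         junction_height = g$z0h,
         rim_level = g$Zt,
         junction_line = list(point = c(-g$A, 0, g$z0h),
                              direction = c(1, 0, 0)),
         seed_points = list(
           radius = c(0, 0, g$z0h / 2),
           ulna = c(g$ulnaBoneR + spec@ulnaThickness / 2, 0,
                    (g$z0h + g$Zt) / 2),
           humerus = c(0, 0, min(g$zcap, g$zlim[2] - 1)))))
}

#' Generate a reproducible cohort of phantom specs
#'
#' Head radii and cartilage thicknesses are drawn uniformly: the coronal
#' subchondral semi-axis from 9.4-10.4 mm (sagittal 0.1-0.5 mm larger),
#' the rim cartilage thickness from `cartilage_range`, and the dish
#' cartilage as a `dish_to_rim` fraction of the rim thickness (peripheral
#' rim cartilage is thicker than central dish cartilage, which is what
#' makes plain CT underestimate the disc depth).  Apposed surfaces share
#' a thickness (notch = rim, capitellum = dish), the regime in which
#' halving the subchondral gap recovers the cartilage surface exactly.
#'
#' @param base_spec a [PhantomSpec-class] supplying all other fields.
#' @param n cohort size (`>= 1`).
#' @param cartilage_range `c(lo, hi)` mm with `0 <= lo <= hi <= 3.5`.
#' @param dish_to_rim `c(lo, hi)` range of the dish-to-rim thickness
#'   ratio; use `c(1, 1)` for uniform cartilage on all surfaces.
#' @param seed integer; the cohort is reproducible given the seed.
#' @return list of `n` [PhantomSpec-class] objects.
#' @export
generateCohort <- function(base_spec = phantomSpec(), n = 8,
                           cartilage_range = c(0.5, 2.0),
                           dish_to_rim = c(0.35, 0.6), seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (cartilage_range[1] < 0 || cartilage_range[2] > 3.5 ||
      cartilage_range[1] > cartilage_range[2])
    stop("cartilage_range must satisfy 0 <= lo <= hi <= 3.5 mm")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    a <- runif(1, 9.4, 10.4)
    b <- a + runif(1, 0.1, 0.5)
    t_rim <- runif(1, cartilage_range[1], cartilage_range[2])
    t_dish <- t_rim * runif(1, dish_to_rim[1], dish_to_rim[2])
    phantomSpec(headCoronalRadius = a, headSagittalRadius = b,
                rimCartilageT = t_rim, notchCartilageT = t_rim,
                dishCartilageT = t_dish, capitellumCartilageT = t_dish,
                headHeight = base_spec@headHeight,
                dishSphereRadius = base_spec@dishSphereRadius,
                dishDepth = base_spec@dishDepth,
                neckRadius = base_spec@neckRadius,
                shaftLength = base_spec@shaftLength,
                tuberosityAzimuthDeg = base_spec@tuberosityAzimuthDeg,
                tuberosityHeight = base_spec@tuberosityHeight,
                capitellumRadius = base_spec@capitellumRadius,
                fluidGap = base_spec@fluidGap,
                articularSectorDeg = base_spec@articularSectorDeg,
                notchHalfAngleDeg = base_spec@notchHalfAngleDeg,
                ulnaThickness = base_spec@ulnaThickness,
                huBone = base_spec@huBone,
                huCartilage = base_spec@huCartilage,
                huSoft = base_spec@huSoft, noiseSd = base_spec@noiseSd,
                spacing = base_spec@spacing,
                seed = sample.int(.Machine$integer.max %/% 2, 1))
  })
}
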