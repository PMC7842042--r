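# Volume-level cartilage compensation: per-axial-slice reform at the
# proximal radioulnar joint, rigid proximal translation of the articular
# patch at the radiocapitellar joint, and the end-to-end orchestrator.

#' Cartilage compensation at the proximal radioulnar joint
#'
#' For every axial slice in which both the radial head and the ulna appear
#' and an articular alteration is detectable, the articular portion of the
#' head contour is translated along the reforming axis by half the measured
#' subchondral gap and the added area is rasterised back into the mask.
#' Slices without detectable apposition pass through unchanged.
#'
#' @param head_mask,ulna_mask [BinaryMask-class] objects on a common grid.
#' @param deviation_tol junction detection tolerance (mm); default
#'   `max(0.3, 1.5 * in-plane voxel)`.
#' @param persistence_deg junction persistence arc, see
#'   [detectAnaJunctions()].
#' @param max_gap plausibility bound (mm) on the subchondral gap: slices
#'   measuring a larger gap (degenerate contours near the rim crest, or a
#'   ray escaping through a broken ring section) are skipped, as are
#'   slices whose reform would produce an invalid contour.
#' @return list with `mask` (the reformed [BinaryMask-class], a superset of
#'   the input head mask) and `slices`, a data frame with one row per
#'   reformed slice: `z_mm, j1x, j1y, j2x, j2y, gap_mm, delta_mm`.
#' @export
cirmRadioulnar <- function(head_mask, ulna_mask, deviation_tol = NULL,
                           persistence_deg = 5, max_gap = 8) {
  if (!any(ulna_mask@data)) stop("ulna mask is empty")
  if (!any(head_mask@data)) stop("head mask is empty")
  if (any(dim(head_mask@data) != dim(ulna_mask@data)) ||
      max(abs(head_mask@spacing - ulna_mask@spacing)) > 1e-9)
    stop("head and ulna masks must share one grid")
  sp <- head_mask@spacing; org <- head_mask@origin
  d <- dim(head_mask@data)
  out <- head_mask@data
  rows <- list()
  n_apposed <- 0L
  for (k in seq_len(d[3])) {
    hs <- head_mask@data[, , k]
    us <- ulna_mask@data[, , k]
    if (!any(hs) || !any(us)) next
    n_apposed <- n_apposed + 1L
    ctr <- tryCatch(
      extractAxialContour(head_mask, "radius", k),
      error = function(e) NULL)
    if (is.null(ctr) || nrow(ctr@points) < 8) next
    hc <- colMeans(voxelToWorld(head_mask,
             cbind(which(hs, arr.ind = TRUE) - 1L, 0))[, 1:2, drop = FALSE])
    uc <- colMeans(voxelToWorld(ulna_mask,
             cbind(which(us, arr.ind = TRUE) - 1L, 0))[, 1:2, drop = FALSE])
    od <- uc - hc
    if (sqrt(sum(od^2)) < 1e-9) next
    jn <- tryCatch(
      detectAnaJunctions(ctr, od, deviation_tol = deviation_tol,
                         inplane_voxel = min(sp[1:2]),
                         persistence_deg = persistence_deg),
      error = function(e) {
        if (grepl("no articular alteration|implausible", conditionMessage(e)))
          NULL else stop(e)
      })
    if (is.null(jn)) next
    ax <- reformingAxis(jn, inplane_voxel = min(sp[1:2]))
    uctr <- extractAxialContour(ulna_mask, "ulna", k)
    gm <- tryCatch(subchondralGap(ctr, uctr, ax), error = function(e) {
      if (grepl("not apposed", conditionMessage(e))) NULL else stop(e)
    })
    if (is.null(gm) || gm@gap > max_gap) next
    delta <- gm@gap / 2
    ref <- tryCatch(reformSlice(ctr, jn, ax, delta), error = function(e) {
      if (grepl("invalid contour", conditionMessage(e))) NULL else stop(e)
    })
    if (is.null(ref)) next # degenerate slice, skipped (logged by absence)
    if (delta > 0) {
      fillR <- .cct_polygon_fill(ref@points, org[1], org[2], sp[1], sp[2],
                                 d[1], d[2])
      fillO <- .cct_polygon_fill(ctr@points, org[1], org[2], sp[1], sp[2],
                                 d[1], d[2])
      out[, , k] <- out[, , k] | (fillR & !fillO)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(z_mm = ctr@z, j1x = jn@j1[1], j1y = jn@j1[2],
                 j2x = jn@j2[1], j2y = jn@j2[2],
                 gap_mm = gm@gap, delta_mm = delta)
  }
  if (n_apposed == 0L)
    stop("no slice with radioulnar apposition found")
  # apposed slices without a detectable articular alteration (no
  # cartilage recession) legitimately pass through unchanged
  slices <- if (length(rows)) do.call(rbind, rows) else
    data.frame(z_mm = numeric(), j1x = numeric(), j1y = numeric(),
               j2x = numeric(), j2y = numeric(), gap_mm = numeric(),
               delta_mm = numeric())
  list(mask = BinaryMask(out, spacing = sp, origin = org), slices = slices)
}

#' Cartilage compensation at the radiocapitellar joint
#'
#' The articular patch is the upward-facing head surface that sees the
#' capitellum along `frame_direction`; the subchondral gap is measured by
#' the ray from the dish's deepest point and the patch is rigidly
#' translated by half that gap toward the capitellum (one rigid 3-D
#' translation, not per-slice).  A linear taper blends the patch border
#' into untouched surface.
#'
#' @param head_mask,capitellum_mask [BinaryMask-class] objects on a common
#'   grid.
#' @param frame_direction unit vector from the articular dish toward the
#'   capitellum.  Must be aligned with the grid's axial axis
#'   (`c(0, 0, 1)` or `c(0, 0, -1)`): the compensation translates voxel
#'   columns along the scanner axis.
#' @param dish_window depth (mm) of the surface band below the most
#'   proximal head point that counts as articular patch; columns whose
#'   top surface lies deeper (shaft, tuberosity) never belong to the dish
#'   even when the capitellum is above them.
#' @return list with `mask` (reformed [BinaryMask-class]), `gap_mm`,
#'   `delta_mm` and `dish_point` (mm, the deepest subchondral dish point).
#' @export
cirmRadiocapitellar <- function(head_mask, capitellum_mask,
                                frame_direction = c(0, 0, 1),
                                dish_window = 6) {
  if (!any(capitellum_mask@data)) stop("capitellum mask is empty")
  fd <- frame_direction / sqrt(sum(frame_direction^2))
  if (max(abs(fd[1:2])) > 1e-6)
    stop("frame_direction must be aligned with the grid's axial axis")
  flip <- fd[3] < 0
  H <- head_mask@data; C <- capitellum_mask@data
  d <- dim(H)
  if (flip) { H <- H[, , d[3]:1, drop = FALSE]; C <- C[, , d[3]:1, drop = FALSE] }
  sz <- head_mask@spacing[3]
  nz <- d[3]
  top <- matrix(0L, d[1], d[2])
  capbot <- matrix(NA_integer_, d[1], d[2])
  for (k in seq_len(nz)) {
    top[H[, , k]] <- k
    kk <- nz + 1L - k
    capbot[C[, , kk]] <- kk
  }
  patch <- top > 0L & !is.na(capbot) & capbot > top
  if (!any(patch)) stop("joint not apposed: no head column sees the capitellum")
  # articular patch lives in the proximal surface band; drop columns whose
  # top is deeper than the dish can be (shaft or tuberosity surface)
  patch <- patch & top >= max(top[patch]) - ceiling(dish_window / sz)
  if (!any(patch)) stop("joint not apposed: no head column sees the capitellum")
  # deepest dish point = lowest top surface among patch columns
  kmin <- min(top[patch])
  cand <- which(patch & top == kmin, arr.ind = TRUE)
  dish_ij <- cand[which.min(rowSums(sweep(cand, 2,
                colMeans(cand))^2)), , drop = TRUE]
  ktop <- top[dish_ij[1], dish_ij[2]]
  kcap <- capbot[dish_ij[1], dish_ij[2]]
  # sub-voxel iso-surface positions: half a voxel beyond the last centres
  gap <- (kcap - ktop) * sz - sz
  if (gap < 0) stop("overlapping masks at the radiocapitellar joint")
  delta <- gap / 2
  nvox <- as.integer(round(delta / sz))
  raise <- matrix(0L, d[1], d[2])
  raise[patch] <- nvox
  if (nvox > 0L) {
    # taper over non-patch head columns adjacent to the patch
    repeat {
      grown <- raise
      cur <- which(raise > 1L, arr.ind = TRUE)
      changed <- FALSE
      for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ni <- cur[, 1] + dd[1]; nj <- cur[, 2] + dd[2]
        ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2]
        idx <- cbind(ni[ok], nj[ok])
        vals <- raise[cur[ok, , drop = FALSE]] - 1L
        tgt <- grown[idx]
        hed <- top[idx] > 0L & !patch[idx]
        upd <- hed & vals > tgt
        if (any(upd)) {
          grown[idx[upd, , drop = FALSE]] <- vals[upd]
          changed <- TRUE
        }
      }
      if (!changed) break
      raise <- grown
    }
    out <- H
    cols <- which(raise > 0L & top > 0L, arr.ind = TRUE)
    for (r in seq_len(nrow(cols))) {
      i <- cols[r, 1]; j <- cols[r, 2]
      k1 <- min(nz, top[i, j] + raise[i, j])
      out[i, j, (top[i, j] + 1L):k1] <- TRUE
    }
  } else out <- H
  if (flip) out <- out[, , d[3]:1, drop = FALSE]
  dishp <- voxelToWorld(head_mask,
             cbind(dish_ij[1] - 1L, dish_ij[2] - 1L,
                   (if (flip) nz - ktop else ktop - 1L)))
  dishp[3] <- dishp[3] + (if (flip) -1 else 1) * sz / 2
  list(mask = BinaryMask(out, spacing = head_mask@spacing,
                         origin = head_mask@origin),
       gap_mm = gap, delta_mm = delta, dish_point = as.numeric(dishp))
}

#' Run the full cartilage-reproducing reconstruction
#'
#' Segments bone by HU threshold, labels the three bones from seeds, builds
#' the bone-only (CT) surface mesh, applies the radioulnar compensation
#' slice by slice, then the radiocapitellar compensation on the updated
#' solid, and meshes the result.
#'
#' @param volume a [CTVolume-class] containing proximal radius, proximal
#'   ulna and distal humerus.
#' @param seeds named list of physical seed points with names `radius`,
#'   `ulna`, `humerus` (see [labelBones()]).
#' @param hu_low,hu_high bone segmentation window (HU).
#' @param deviation_tol junction tolerance passed to [cirmRadioulnar()].
#' @return list with `ct_mesh`, `cirm_mesh` ([TriMesh-class]), `ct_mask`,
#'   `cirm_mask`, `slices` (per-slice junction/gap/delta table) and
#'   `radiocapitellar` (gap/delta info).
#' @export
runCIRM <- function(volume, seeds, hu_low = 250, hu_high = 2500,
                    deviation_tol = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  need <- c("radius", "ulna", "humerus")
  if (!all(need %in% names(seeds)))
    stop("[labeling] seeds must include radius, ulna and humerus")
  mask <- stage("segmentation", thresholdBone(volume, hu_low, hu_high))
  lab <- stage("labeling", labelBones(mask, seeds[need]))
  radius <- boneMask(lab, "radius")
  ulna <- boneMask(lab, "ulna")
  hum <- boneMask(lab, "humerus")
  ct_mesh <- stage("meshing", meshFromMask(radius))
  ru <- stage("radioulnar", cirmRadioulnar(radius, ulna,
                                           deviation_tol = deviation_tol))
  zr <- meanMaskZ(radius); zh <- meanMaskZ(hum)
  fd <- c(0, 0, sign(zh - zr))
  rc <- stage("radiocapitellar", cirmRadiocapitellar(ru$mask, hum, fd))
  cirm_mesh <- stage("meshing", meshFromMask(rc$mask))
  list(ct_mesh = ct_mesh, cirm_mesh = cirm_mesh,
       ct_mask = radius, cirm_mask = rc$mask,
       slices = ru$slices,
       radiocapitellar = rc[c("gap_mm", "delta_mm", "dish_point")])
}

meanMaskZ <- function(mask) {
  ks <- which(apply(mask@data, 3, any))
  mask@origin[3] + (mean(ks) - 1) * mask@spacing[3]
}
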