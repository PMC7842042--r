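# Rigid surface registration on the tuberosity-diaphyseal region and RMS
# surface deviation between aligned models.

#' RegionSpec: a vertex-subset specification on a mesh
#'
#' Either all vertices on the distal side of a plane (the tuberosity +
#' diaphysis side of the head-neck junction) or an explicit vertex id set.
#' Exactly one mode is populated.
#'
#' @slot mode `"below-plane"` or `"vertex-ids"`.
#' @slot plane list with `point` and `normal` (length-3) for
#'   `"below-plane"`; vertices with negative signed distance are selected.
#' @slot ids integer vertex ids for `"vertex-ids"`.
#' @aliases RegionSpec
#' @export
setClass("RegionSpec",
  representation(mode = "character", plane = "list", ids = "integer"),
  validity = function(object) {
    if (!object@mode %in% c("below-plane", "vertex-ids"))
      return("mode must be below-plane or vertex-ids")
    if (object@mode == "below-plane" &&
        !all(c("point", "normal") %in% names(object@plane)))
      return("below-plane mode needs plane$point and plane$normal")
    if (object@mode == "vertex-ids" && length(object@ids) == 0)
      return("vertex-ids mode needs at least one id")
    TRUE
  })

#' Construct a RegionSpec
#' @param plane list with `point`, `normal` (length-3 mm / unit) selecting
#'   vertices on the negative-normal side; or NULL.
#' @param ids explicit integer vertex ids; or NULL.  Exactly one of
#'   `plane`/`ids` must be given.
#' @return A [RegionSpec-class].
#' @export
RegionSpec <- function(plane = NULL, ids = NULL) {
  if (is.null(plane) == is.null(ids))
    stop("give exactly one of plane or ids")
  if (!is.null(plane))
    new("RegionSpec", mode = "below-plane", plane = plane, ids = integer())
  else
    new("RegionSpec", mode = "vertex-ids", plane = list(),
        ids = as.integer(ids))
}

#' Select the vertex subset of a region
#'
#' @param mesh a [TriMesh-class].
#' @param spec a [RegionSpec-class]; for `"below-plane"` the vertices with
#'   signed distance `< 0` to the plane (distal side) are selected.
#' @return Integer vector of vertex ids.
#' @export
selectRegion <- function(mesh, spec) {
  if (spec@mode == "vertex-ids") {
    ids <- spec@ids
    if (any(ids < 1 | ids > nrow(mesh@vertices)))
      stop("vertex ids out of range")
  } else {
    nrm <- spec@plane$normal / sqrt(sum(spec@plane$normal^2))
    sd <- as.numeric(sweep(mesh@vertices, 2, spec@plane$point) %*% nrm)
    ids <- which(sd < 0)
  }
  if (length(ids) == 0) stop("region selection is empty")
  ids
}

kabsch <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  sv <- svd(H)
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  RigidTransform(R, cd - as.numeric(R %*% cs))
}

principalAxes <- function(pts) {
  e <- eigen(stats::cov(pts), symmetric = TRUE)
  e$vectors
}

faceNormals <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

# Linearised point-to-plane alignment step: minimise sum over
# correspondences of ((p + w x p + t - q) . n)^2 and exponentiate w.
pointToPlaneStep <- function(p, q, n) {
  cxn <- cbind(p[, 2] * n[, 3] - p[, 3] * n[, 2],
               p[, 3] * n[, 1] - p[, 1] * n[, 3],
               p[, 1] * n[, 2] - p[, 2] * n[, 1])
  A <- cbind(cxn, n)
  b <- rowSums((q - p) * n)
  x <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                error = function(e) NULL)
  if (is.null(x)) return(NULL)
  w <- x[1:3]; tt <- x[4:6]
  th <- sqrt(sum(w^2))
  R <- if (th < 1e-12) diag(3) else {
    k <- w / th
    K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  RigidTransform(R, as.numeric(tt))
}

#' Rigid iterative-closest-point registration
#'
#' Aligns `source` to `target` using point-to-point ICP with
#' correspondences restricted to the registration region (radial tuberosity
#' and diaphyseal surface).  Initialisation is deterministic: centroid
#' alignment plus principal axes, with the axis-sign ambiguity resolved by
#' the combination giving the lowest initial region RMS.
#'
#' @param source,target [TriMesh-class] objects of the same specimen.
#' @param region a [RegionSpec-class] evaluated on `source`.
#' @param max_iter iteration cap.
#' @param tol_mm stop when the region RMS improves by less than this.
#' @param subsample use at most this many region vertices per iteration
#'   (deterministic thinning), keeping large meshes tractable.
#' @return A [RigidTransform-class] mapping source onto target, with
#'   attributes `rms` (final region RMS, mm), `iterations`, and `converged`.
#'   Non-convergence yields a warning, not an error.
#' @export
icpRigid <- function(source, target, region, max_iter = 100, tol_mm = 1e-5,
                     subsample = 6000) {
  ids <- selectRegion(source, region)
  pts <- source@vertices[ids, , drop = FALSE]
  if (nrow(pts) < 3) stop("degenerate region: fewer than 3 vertices")
  if (qr(sweep(pts, 2, colMeans(pts)))$rank < 2)
    stop("degenerate region: collinear vertices")
  if (nrow(pts) > subsample)
    pts <- pts[seq(1, nrow(pts), length.out = subsample), , drop = FALSE]
  tv <- target@vertices; tf <- target@faces
  regionRms <- function(tr) {
    p <- applyTransform(tr, pts)
    sqrt(mean(.cct_nearest_on_surface(p, tv, tf)$distance^2))
  }
  # deterministic initialisation: identity (models already near alignment)
  # or centroids + principal axes, whichever starts with the lower RMS
  es <- principalAxes(pts)
  et <- principalAxes(tv)
  tr0 <- RigidTransform()
  best <- list(tr = tr0, rms = regionRms(tr0))
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    E <- es %*% diag(c(s1, s2, s1 * s2 * sign(det(es)) * sign(det(et))))
    R0 <- et %*% t(E)
    if (det(R0) < 0) next
    tr0 <- RigidTransform(R0, colMeans(tv) - as.numeric(R0 %*% colMeans(pts)))
    r0 <- regionRms(tr0)
    if (is.null(best) || r0 < best$rms) best <- list(tr = tr0, rms = r0)
  }
  # iterate: a linearised point-to-plane step (fast on smooth, sliding-
  # prone surfaces) accepted only when it does not increase the point
  # RMS, falling back to the point-to-point Kabsch step otherwise, so the
  # region RMS never increases between iterations
  tnorm <- faceNormals(tv, tf)
  tr <- best$tr
  p <- applyTransform(tr, pts)
  nn <- .cct_nearest_on_surface(p, tv, tf)
  rms <- sqrt(mean(nn$distance^2))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    improved <- FALSE
    for (step_fun in list(
      function() pointToPlaneStep(p, nn$point, tnorm[nn$face, , drop = FALSE]),
      function() kabsch(p, nn$point))) {
      st <- step_fun()
      if (is.null(st)) next
      tr_try <- composeTransform(st, tr)
      p_try <- applyTransform(tr_try, pts)
      nn_try <- .cct_nearest_on_surface(p_try, tv, tf)
      rms_try <- sqrt(mean(nn_try$distance^2))
      if (rms_try <= rms + 1e-15) {
        improved <- rms - rms_try >= tol_mm
        tr <- tr_try; p <- p_try; nn <- nn_try; rms <- rms_try
        break
      }
    }
    if (!improved) {
      # rotation about a near-symmetric region axis (the diaphysis) is
      # badly conditioned for ICP: polish each principal-axis rotation
      # mode by direct 1-D minimisation of the region RMS
      axes <- principalAxes(p)
      cen <- colMeans(p)
      best_polish <- NULL
      for (col in 1:3) {
        ax <- axes[, col]
        rotAbout <- function(theta) {
          K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]),
                     c(-ax[2], ax[1], 0))
          R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
          RigidTransform(R, cen - as.numeric(R %*% cen))
        }
        opt <- stats::optimize(
          function(theta) regionRms(composeTransform(rotAbout(theta), tr)),
          c(-25, 25) * pi / 180, tol = 1e-5)
        if (is.null(best_polish) || opt$objective < best_polish$rms)
          best_polish <- list(rms = opt$objective,
                              tr = composeTransform(rotAbout(opt$minimum), tr))
      }
      if (best_polish$rms < rms - tol_mm && it < max_iter) {
        tr <- best_polish$tr
        p <- applyTransform(tr, pts)
        nn <- .cct_nearest_on_surface(p, tv, tf)
        rms <- sqrt(mean(nn$distance^2))
        next
      }
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("ICP did not converge within ", max_iter, " iterations")
  structure(tr, rms = rms, iterations = it, converged = converged)
}

#' RMS surface deviation between two aligned meshes
#'
#' For each region vertex of `mesh_a`, the distance to the nearest point on
#' the surface of `mesh_b` (point-to-triangle, not vertex-to-vertex); the
#' overall difference is the root mean square of those distances.  The
#' deviation is asymmetric: `mesh_a` is the model under test, `mesh_b` the
#' gold standard.
#'
#' @param mesh_a,mesh_b [TriMesh-class] objects, already registered.
#' @param region optional [RegionSpec-class] on `mesh_a` (e.g. the radial
#'   head); default all vertices.
#' @param symmetric if TRUE also measures b-to-a and reports the larger RMS.
#' @return list with `rms` (mm) and `mesh`: `mesh_a` annotated with the
#'   per-vertex distance as its vertex scalar (NA outside the region), the
#'   usual deviation colormap input.
#' @export
rmsDeviation <- function(mesh_a, mesh_b, region = NULL, symmetric = FALSE) {
  ids <- if (is.null(region)) seq_len(nrow(mesh_a@vertices))
         else selectRegion(mesh_a, region)
  if (length(ids) == 0) stop("empty deviation region")
  d <- .cct_nearest_on_surface(mesh_a@vertices[ids, , drop = FALSE],
                               mesh_b@vertices, mesh_b@faces)$distance
  rms <- sqrt(mean(d^2))
  if (symmetric) {
    d2 <- .cct_nearest_on_surface(mesh_b@vertices, mesh_a@vertices,
                                  mesh_a@faces)$distance
    rms <- max(rms, sqrt(mean(d2^2)))
  }
  sc <- rep(NA_real_, nrow(mesh_a@vertices))
  sc[ids] <- d
  list(rms = rms,
       mesh = new("TriMesh", vertices = mesh_a@vertices,
                  faces = mesh_a@faces, vertexScalar = sc))
}
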