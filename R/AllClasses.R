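#' @importFrom methods new validObject is slot
#' @importFrom stats sd median pchisq pnorm runif rnorm setNames
#' @importFrom utils write.csv head tail
#' @useDynLib ChondroCT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' CTVolume: a 3-D scalar grid of Hounsfield units
#'
#' The voxel grid underlying every stage of the pipeline.  Axial slices are
#' constant-index planes along the third array index.  Physical coordinates
#' follow the voxel-centre convention: the centre of voxel `(i, j, k)`
#' (0-based) sits at `origin + c(i, j, k) * spacing` millimetres.
#'
#' @slot data 3-D numeric array of HU values (finite).
#' @slot spacing numeric length-3, voxel edge lengths in mm (all `> 0`).
#' @slot origin numeric length-3, physical position (mm) of the centre of
#'   voxel `(0, 0, 0)`.
#' @aliases CTVolume
#' @export
setClass("CTVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive numbers (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("origin must be 3 finite numbers (mm)")
    if (any(!is.finite(object@data))) return("HU data must be finite")
    TRUE
  })

#' Construct a CTVolume
#'
#' @param data 3-D numeric array of HU values.
#' @param spacing voxel spacing `(sx, sy, sz)` in mm.
#' @param origin physical coordinate (mm) of the centre of voxel `(0,0,0)`.
#' @return A [CTVolume-class] object.
#' @export
CTVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("CTVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' BinaryMask: a boolean voxel grid on the geometry of its source volume
#'
#' @slot data 3-D logical array.
#' @slot spacing,origin as in [CTVolume-class].
#' @aliases BinaryMask
#' @export
setClass("BinaryMask",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
    if (!is.logical(object@data)) return("mask data must be logical")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive numbers (mm)")
    if (length(object@origin) != 3L) return("origin must have length 3")
    TRUE
  })

#' Construct a BinaryMask
#' @param data 3-D logical array.
#' @param spacing,origin grid geometry, see [CTVolume()].
#' @return A [BinaryMask-class] object.
#' @export
BinaryMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("BinaryMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' LabeledMask: integer-labelled bone regions on a voxel grid
#'
#' Produced by [labelBones()]; label `l` marks the connected component
#' holding seed `l`, `0` is background.
#'
#' @slot data 3-D integer array of label ids.
#' @slot labels character vector naming the label ids in order (e.g.
#'   `c("radius", "ulna", "humerus")`).
#' @slot spacing,origin as in [CTVolume-class].
#' @aliases LabeledMask
#' @export
setClass("LabeledMask",
  representation(data = "array", labels = "character",
                 spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
    mx <- max(object@data)
    if (mx > length(object@labels)) return("label id exceeds labels length")
    TRUE
  })

#' TriMesh: a triangle surface mesh in physical millimetres
#'
#' @slot vertices numeric matrix `n x 3` of vertex positions (mm).
#' @slot faces integer matrix `m x 3` of 1-based vertex indices.
#' @slot vertexScalar optional numeric of length `n` carrying one value per
#'   vertex (used for deviation colormaps, in mm).
#' @aliases TriMesh
#' @export
setClass("TriMesh",
  representation(vertices = "matrix", faces = "matrix",
                 vertexScalar = "numericOrNULL"),
  validity = function(object) {
    v <- object@vertices; f <- object@faces
    if (ncol(v) != 3L) return("vertices must be n x 3")
    if (nrow(f) > 0 && ncol(f) != 3L) return("faces must be m x 3")
    if (nrow(f) > 0 && (min(f) < 1L || max(f) > nrow(v)))
      return("face indices out of range")
    if (!is.null(object@vertexScalar) &&
        length(object@vertexScalar) != nrow(v))
      return("vertexScalar length must equal vertex count")
    TRUE
  })

#' Construct a TriMesh
#'
#' Degenerate (zero-area) faces are dropped at construction.
#'
#' @param vertices numeric `n x 3` matrix (mm).
#' @param faces integer `m x 3` matrix of 1-based indices.
#' @param vertexScalar optional per-vertex numeric.
#' @return A [TriMesh-class] object.
#' @export
TriMesh <- function(vertices, faces, vertexScalar = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0) {
    a <- vertices[faces[, 1], , drop = FALSE]
    ab <- vertices[faces[, 2], , drop = FALSE] - a
    ac <- vertices[faces[, 3], , drop = FALSE] - a
    cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
                ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
                ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
    area2 <- sqrt(rowSums(cr^2))
    faces <- faces[area2 > 1e-14, , drop = FALSE]
  }
  new("TriMesh", vertices = vertices, faces = faces,
      vertexScalar = vertexScalar)
}

#' RigidTransform: a proper rigid motion of 3-space
#'
#' Maps a point `p` to `rotation %*% p + translation`.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric length-3 (mm).
#' @aliases RigidTransform
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
    if (max(abs(R %*% t(R) - diag(3))) > 1e-9)
      return("rotation is not orthonormal (R R^T != I within 1e-9)")
    if (abs(det(R) - 1) > 1e-9) return("det(rotation) must be +1 within 1e-9")
    if (length(object@translation) != 3L) return("translation must have length 3")
    TRUE
  })

#' Construct a RigidTransform
#' @param rotation 3x3 orthonormal matrix, `det = +1`.
#' @param translation length-3 numeric (mm).
#' @return A [RigidTransform-class] object.
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' SliceContour: closed planar polygon of a bone cross-section
#'
#' An ordered counter-clockwise polygon (first point not repeated) tracing
#' the outer boundary of one bone in one axial slice, in physical mm.
#'
#' @slot points numeric `n x 2` matrix of in-plane coordinates (mm).
#' @slot z physical height of the slice (mm).
#' @slot boneLabel one of `"radius"`, `"ulna"`, `"humerus"`.
#' @aliases SliceContour
#' @export
setClass("SliceContour",
  representation(points = "matrix", z = "numeric", boneLabel = "character"),
  validity = function(object) {
    p <- object@points
    if (ncol(p) != 2L) return("points must be n x 2")
    if (nrow(p) < 4L) return("a contour needs at least 4 points")
    if (isTRUE(all.equal(p[1, ], p[nrow(p), ])))
      return("first point must not be repeated at the end")
    if (polygonArea(p) <= 0) return("contour must be counter-clockwise")
    TRUE
  })

#' Construct a SliceContour
#' @param points `n x 2` matrix (mm), closed polygon without repeated endpoint.
#'   Re-oriented counter-clockwise if needed.
#' @param z slice height (mm).
#' @param boneLabel bone name.
#' @return A [SliceContour-class] object.
#' @export
SliceContour <- function(points, z = 0, boneLabel = "radius") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) >= 2 &&
      isTRUE(all.equal(points[1, ], points[nrow(points), ])))
    points <- points[-nrow(points), , drop = FALSE]
  if (nrow(points) >= 3 && polygonArea(points) < 0)
    points <- points[nrow(points):1, , drop = FALSE]
  new("SliceContour", points = points, z = as.numeric(z),
      boneLabel = boneLabel)
}

#' ReferenceFrame: measurement frame fixed on the gold-standard model
#'
#' Disc centre plus an orthonormal right-handed triad.  The coronal plane
#' contains the disc centre, the head's long axis and the tuberosity
#' direction; diameters are taken at `axialLevel` along the axial normal.
#'
#' @slot discCenter numeric length-3 (mm).
#' @slot coronalNormal,sagittalNormal,axialNormal orthonormal unit vectors;
#'   `coronalNormal x sagittalNormal = axialNormal`.
#' @slot axialLevel scalar position (mm) along `axialNormal` at which
#'   diameters are measured.
#' @slot junctionLine list with elements `point` (length-3) and `direction`
#'   (length-3 unit), the head-neck junction line in the coronal plane, or
#'   an empty list when not set.
#' @aliases ReferenceFrame
#' @export
setClass("ReferenceFrame",
  representation(discCenter = "numeric", coronalNormal = "numeric",
                 sagittalNormal = "numeric", axialNormal = "numeric",
                 axialLevel = "numeric", junctionLine = "list"),
  validity = function(object) {
    B <- cbind(object@coronalNormal, object@sagittalNormal, object@axialNormal)
    if (any(dim(B) != c(3, 3))) return("normals must be length-3 vectors")
    if (max(abs(crossprod(B) - diag(3))) > 1e-9)
      return("frame axes are not orthonormal within 1e-9")
    if (abs(det(B) - 1) > 1e-9) return("frame must be right-handed")
    TRUE
  })

#' MorphometricReport: the five radial-head parameters for one model
#'
#' Coronal and sagittal diameter of the head, medial and lateral rim
#' thickness above the head-neck junction line, and articular disc depth,
#' all in millimetres.
#'
#' @slot coronalDiameter,sagittalDiameter,medialThickness,lateralThickness,discDepth
#'   numeric scalars (mm, all `>= 0`).
#' @aliases MorphometricReport
#' @export
setClass("MorphometricReport",
  representation(coronalDiameter = "numeric", sagittalDiameter = "numeric",
                 medialThickness = "numeric", lateralThickness = "numeric",
                 discDepth = "numeric"),
  validity = function(object) {
    v <- c(object@coronalDiameter, object@sagittalDiameter,
           object@medialThickness, object@lateralThickness, object@discDepth)
    if (any(v < 0)) return("all parameters must be >= 0")
    TRUE
  })

#' Construct a MorphometricReport
#' @param coronalDiameter,sagittalDiameter,medialThickness,lateralThickness,discDepth
#'   parameter values in mm.
#' @return A [MorphometricReport-class] object.  A warning (not an error) is
#'   raised when a diameter does not exceed both thicknesses, which is
#'   anatomically implausible.
#' @export
MorphometricReport <- function(coronalDiameter, sagittalDiameter,
                               medialThickness, lateralThickness, discDepth) {
  obj <- new("MorphometricReport",
             coronalDiameter = coronalDiameter,
             sagittalDiameter = sagittalDiameter,
             medialThickness = medialThickness,
             lateralThickness = lateralThickness,
             discDepth = discDepth)
  if (min(coronalDiameter, sagittalDiameter) <=
      max(medialThickness, lateralThickness))
    warning("diameters do not exceed rim thicknesses; input may be implausible")
  obj
}

#' Convert a MorphometricReport to a one-row data frame
#' @param x a [MorphometricReport-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with the five `*_mm` columns.
#' @export
as.data.frame.MorphometricReport <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(coronal_diameter_mm = x@coronalDiameter,
             sagittal_diameter_mm = x@sagittalDiameter,
             medial_thickness_mm = x@medialThickness,
             lateral_thickness_mm = x@lateralThickness,
             disc_depth_mm = x@discDepth)
}

# ---- accessors ------------------------------------------------------------

#' Grid and mesh accessors
#'
#' Slot access for the voxel and mesh containers.
#'
#' @param x a [CTVolume-class], [BinaryMask-class], [LabeledMask-class]
#'   (grid accessors) or [TriMesh-class] (mesh accessors).
#' @return `voxelData`: the 3-D array; `voxelSpacing`, `voxelOrigin`:
#'   length-3 numerics (mm); `meshVertices`: `n x 3` matrix;
#'   `meshFaces`: `m x 3` integer matrix; `vertexScalar`: numeric or NULL.
#' @name accessors
NULL

#' @rdname accessors
#' @export
voxelData <- function(x) x@data
#' @rdname accessors
#' @export
voxelSpacing <- function(x) x@spacing
#' @rdname accessors
#' @export
voxelOrigin <- function(x) x@origin
#' @rdname accessors
#' @export
meshVertices <- function(x) x@vertices
#' @rdname accessors
#' @export
meshFaces <- function(x) x@faces
#' @rdname accessors
#' @export
vertexScalar <- function(x) x@vertexScalar

#' Map voxel indices to physical coordinates
#'
#' @param grid an object with `spacing`/`origin` slots.
#' @param ijk integer matrix `n x 3` of 0-based voxel indices.
#' @return `n x 3` matrix of physical mm coordinates (voxel centres).
#' @export
voxelToWorld <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk, 2, grid@spacing, `*`), 2, grid@origin, `+`)
}

#' Map physical coordinates to (fractional) voxel indices
#' @param grid an object with `spacing`/`origin` slots.
#' @param xyz numeric matrix `n x 3` of mm coordinates.
#' @return `n x 3` matrix of 0-based fractional voxel indices.
#' @export
worldToVoxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(sweep(xyz, 2, grid@origin, `-`), 2, grid@spacing, `/`)
}

# ---- show methods ---------------------------------------------------------

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("CTVolume: %d x %d x %d voxels, spacing %s mm, HU [%g, %g]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryMask: %d x %d x %d voxels, %d foreground (%.1f%%)\n",
              d[1], d[2], d[3], sum(object@data),
              100 * mean(object@data)))
})

setMethod("show", "LabeledMask", function(object) {
  cnt <- tabulate(object@data[object@data > 0L],
                  nbins = length(object@labels))
  cat("LabeledMask:",
      paste(sprintf("%s=%d", object@labels, cnt), collapse = ", "), "\n")
})

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh: %d vertices, %d faces%s\n",
              nrow(object@vertices), nrow(object@faces),
              if (!is.null(object@vertexScalar)) ", with vertex scalar" else ""))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%s) mm\n",
              ang, paste(format(object@translation, digits = 4), collapse = ", ")))
})

setMethod("show", "SliceContour", function(object) {
  cat(sprintf("SliceContour (%s): %d points at z = %.2f mm, area %.2f mm^2\n",
              object@boneLabel, nrow(object@points), object@z,
              polygonArea(object@points)))
})

setMethod("show", "MorphometricReport", function(object) {
  cat(sprintf(paste0("MorphometricReport: coronal %.2f, sagittal %.2f, ",
                     "medial %.2f, lateral %.2f, depth %.2f (mm)\n"),
              object@coronalDiameter, object@sagittalDiameter,
              object@medialThickness, object@lateralThickness,
              object@discDepth))
})

#' Apply a rigid transform to points or a mesh
#'
#' @param transform a [RigidTransform-class].
#' @param x an `n x 3` point matrix or a [TriMesh-class].
#' @return The transformed points or mesh.
#' @export
applyTransform <- function(transform, x) {
  if (is(x, "TriMesh")) {
    v <- applyTransform(transform, x@vertices)
    return(new("TriMesh", vertices = v, faces = x@faces,
               vertexScalar = x@vertexScalar))
  }
  t(transform@rotation %*% t(x)) +
    matrix(transform@translation, nrow(x), 3, byrow = TRUE)
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b [RigidTransform-class] objects.
#' @return The composition as a [RigidTransform-class].
#' @export
composeTransform <- function(a, b) {
  RigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Signed area of a closed polygon (shoelace formula)
#'
#' Positive for counter-clockwise orientation.
#'
#' @param p `n x 2` matrix of polygon vertices (not closed).
#' @return Signed area in the square of the coordinate unit.
#' @export
polygonArea <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}
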