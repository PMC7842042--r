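# Bone segmentation: Hounsfield thresholding, seeded 26-connectivity
# labelling, per-slice boundary contours and isosurface meshing.

#' Threshold bone by Hounsfield unit
#'
#' Marks voxels with `hu_low <= HU <= hu_high` (both bounds inclusive; the
#' standard bone segmentation window is the closed range 250 to 2500 HU).
#'
#' @param volume a [CTVolume-class].
#' @param hu_low,hu_high inclusive HU bounds; `hu_low` must be `< hu_high`.
#' @return A [BinaryMask-class] on the same grid.
#' @export
thresholdBone <- function(volume, hu_low = 250, hu_high = 2500) {
  if (hu_low >= hu_high) stop("hu_low must be strictly below hu_high")
  BinaryMask(volume@data >= hu_low & volume@data <= hu_high,
             spacing = volume@spacing, origin = volume@origin)
}

#' Label bones from seed points
#'
#' Flood-fills the mask from up to three physical seed points with
#' 26-connectivity.  Each labelled region is one connected component;
#' components containing no seed are dropped.
#'
#' @param mask a [BinaryMask-class].
#' @param seeds named list of physical mm points (e.g.
#'   `list(radius = c(x, y, z), ulna = ..., humerus = ...)`), or an `n x 3`
#'   matrix with rownames.
#' @return A [LabeledMask-class] whose `labels` follow the seed order.
#' @details Errors if a seed lies outside the mask or if two seeds fall in
#'   the same connected component.
#' @export
labelBones <- function(mask, seeds) {
  if (is.matrix(seeds)) {
    nm <- rownames(seeds)
    seeds <- lapply(seq_len(nrow(seeds)), function(i) seeds[i, ])
    names(seeds) <- nm
  }
  if (is.null(names(seeds)) || any(!nzchar(names(seeds))))
    stop("seeds must be named by bone")
  ijk <- round(worldToVoxel(mask, do.call(rbind, seeds)))
  storage.mode(ijk) <- "integer"
  lab <- .cct_label_seeded(as.logical(mask@data), dim(mask@data), ijk)
  new("LabeledMask", data = array(lab, dim(mask@data)),
      labels = names(seeds), spacing = mask@spacing, origin = mask@origin)
}

#' Extract one bone as a BinaryMask
#' @param labeled a [LabeledMask-class].
#' @param bone_label bone name present in `labeled@labels`.
#' @return A [BinaryMask-class].
#' @export
boneMask <- function(labeled, bone_label) {
  id <- match(bone_label, labeled@labels)
  if (is.na(id)) stop("label not present: ", bone_label)
  BinaryMask(labeled@data == id, spacing = labeled@spacing,
             origin = labeled@origin)
}

#' Extract the outer boundary contour of a bone in one axial slice
#'
#' Traces the 0.5 iso-level between foreground and background voxels of the
#' requested bone in slice `slice_index`, in physical mm.  When the slice
#' region has several boundary loops (e.g. a cortical shell around a marrow
#' cavity), the largest-area loop -- the external boundary -- is returned.
#'
#' @param labeled a [LabeledMask-class] or [BinaryMask-class].
#' @param bone_label bone name (ignored for a [BinaryMask-class]).
#' @param slice_index 1-based axial slice index.
#' @return A [SliceContour-class], counter-clockwise.
#' @export
extractAxialContour <- function(labeled, bone_label = NULL, slice_index) {
  if (is(labeled, "LabeledMask")) {
    id <- match(bone_label, labeled@labels)
    if (is.na(id)) stop("label not present: ", bone_label)
    sl <- labeled@data[, , slice_index] == id
  } else {
    sl <- labeled@data[, , slice_index]
    if (is.null(bone_label)) bone_label <- "radius"
  }
  if (!any(sl)) stop("label ", bone_label, " absent in slice ", slice_index)
  poly <- largestIsoLoop(sl, labeled@spacing[1:2], labeled@origin[1:2])
  SliceContour(poly, z = labeled@origin[3] +
                 (slice_index - 1) * labeled@spacing[3],
               boneLabel = bone_label)
}

# Largest-area closed 0.5-iso loop of a logical slice, in physical mm.
largestIsoLoop <- function(sl, spacing2, origin2) {
  nx <- nrow(sl); ny <- ncol(sl)
  pad <- matrix(0, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- sl * 1
  xs <- origin2[1] + ((0:(nx + 1L)) - 1) * spacing2[1]
  ys <- origin2[2] + ((0:(ny + 1L)) - 1) * spacing2[2]
  cl <- grDevices::contourLines(xs, ys, pad, levels = 0.5)
  if (length(cl) == 0) stop("no iso-contour found in slice")
  areas <- vapply(cl, function(cc) {
    p <- cbind(cc$x, cc$y)
    if (nrow(p) > 1 && isTRUE(all.equal(p[1, ], p[nrow(p), ])))
      p <- p[-nrow(p), , drop = FALSE]
    abs(polygonArea(p))
  }, 0)
  p <- cbind(cl[[which.max(areas)]]$x, cl[[which.max(areas)]]$y)
  if (isTRUE(all.equal(p[1, ], p[nrow(p), ]))) p <- p[-nrow(p), , drop = FALSE]
  p
}

#' Triangulated isosurface of a voxel region
#'
#' Extracts the closed, watertight 0.5-level surface between inside and
#' outside voxels using marching tetrahedra (cells are split into six
#' tetrahedra with matching face diagonals, so the surface has no cracks).
#' Coordinates are physical mm.
#'
#' @param mask a [BinaryMask-class], or a [LabeledMask-class] together with
#'   `bone_label`.
#' @param bone_label bone name when `mask` is labelled.
#' @return A [TriMesh-class] with outward-pointing facet orientation.
#' @export
meshFromMask <- function(mask, bone_label = NULL) {
  if (is(mask, "LabeledMask")) mask <- boneMask(mask, bone_label)
  if (!any(mask@data)) stop("empty region: no voxels to mesh")
  d <- dim(mask@data)
  field <- array(0, d + 2L)
  field[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask@data * 1
  res <- .cct_marching_tets(as.numeric(field), dim(field), 0.5,
                            mask@spacing, mask@origin - mask@spacing)
  TriMesh(res$vertices, res$faces)
}

#' Enclosed volume of a closed oriented mesh
#'
#' Divergence-theorem volume (sum of signed tetrahedra against the origin).
#' Positive for outward-oriented watertight surfaces.
#'
#' @param mesh a [TriMesh-class].
#' @return Volume in mm^3.
#' @export
meshVolume <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Check that every mesh edge is shared by exactly two faces
#' @param mesh a [TriMesh-class].
#' @return TRUE when the surface is closed (watertight), FALSE otherwise.
#' @export
isWatertight <- function(mesh) {
  f <- mesh@faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}
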