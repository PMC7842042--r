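# STL (binary and ASCII) and ASCII PLY mesh I/O.  STL stores bare facets:
# topology is rebuilt on read by merging vertices with exactly identical
# coordinates as written.  PLY carries the optional per-vertex scalar as a
# "deviation_mm" property; STL drops it.

#' Write a triangle mesh
#'
#' @param mesh a [TriMesh-class] (non-empty).
#' @param path output file path.
#' @param format `"stl-binary"`, `"stl-ascii"` or `"ply"`.  PLY keeps the
#'   per-vertex scalar (as property `deviation_mm`); STL cannot carry it.
#' @return `path`, invisibly.
#' @export
writeMesh <- function(mesh, path, format = c("stl-binary", "stl-ascii", "ply")) {
  format <- match.arg(format)
  if (nrow(mesh@faces) == 0L) stop("cannot write an empty mesh")
  v <- mesh@vertices; f <- mesh@faces
  if (format == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    has_sc <- !is.null(mesh@vertexScalar)
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z",
             if (has_sc) "property double deviation_mm",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(hdr, con)
    vt <- if (has_sc) cbind(v, mesh@vertexScalar) else v
    writeLines(apply(format(vt, digits = 17, scientific = FALSE,
                            trim = TRUE), 1, paste, collapse = " "), con)
    writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
    return(invisible(path))
  }
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-300)
  if (format == "stl-ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    fmt <- function(m) apply(format(m, digits = 17, scientific = TRUE,
                                    trim = TRUE), 1, paste, collapse = " ")
    writeLines("solid chondroct", con)
    body <- paste0("facet normal ", fmt(nrm), "\n outer loop\n  vertex ",
                   fmt(a), "\n  vertex ", fmt(b), "\n  vertex ", fmt(cc),
                   "\n endloop\nendfacet")
    writeLines(body, con)
    writeLines("endsolid chondroct", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    dat <- t(cbind(nrm, a, b, cc)) # 12 floats per facet
    for (i in seq_len(nrow(f))) {
      writeBin(dat[, i], con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

#' Read a triangle mesh
#'
#' STL facets are welded into a shared-vertex mesh by merging vertices whose
#' written coordinates match exactly.
#'
#' @param path input file.
#' @param format `"auto"` (sniffed), `"stl-binary"`, `"stl-ascii"` or `"ply"`.
#' @return A [TriMesh-class]; PLY `deviation_mm` becomes the vertex scalar.
#' @export
readMesh <- function(path, format = c("auto", "stl-binary", "stl-ascii", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    head8 <- readBin(path, "raw", n = 80)
    txt <- suppressWarnings(rawToChar(head8[head8 != as.raw(0)]))
    format <- if (startsWith(txt, "ply")) "ply"
      else if (grepl("^\\s*solid", txt) && isAsciiStl(path)) "stl-ascii"
      else "stl-binary"
  }
  switch(format,
         "ply" = readPly(path),
         "stl-ascii" = readStlAscii(path),
         "stl-binary" = readStlBinary(path))
}

isAsciiStl <- function(path) {
  # binary STLs may start with "solid" too; require facet keywords in text
  txt <- suppressWarnings(readLines(path, n = 5, warn = FALSE))
  any(grepl("facet|endsolid", txt))
}

weldFacets <- function(tri) {
  # tri: (3*nfacet) x 3 matrix of corner coordinates in facet order
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "|")
  uk <- !duplicated(key)
  ids <- match(key, key[uk])
  verts <- tri[uk, , drop = FALSE]
  faces <- matrix(ids, ncol = 3, byrow = TRUE)
  TriMesh(verts, faces)
}

readStlAscii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed ASCII STL (vertex count ", length(vl),
         " not a multiple of 3): ", path)
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(nums))) stop("malformed ASCII STL coordinates: ", path)
  weldFacets(nums)
}

readStlBinary <- function(path) {
  sz <- file.info(path)$size
  if (sz < 84) stop("truncated binary STL (", sz, " bytes, header needs 84): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  nf <- readBin(con, "integer", size = 4, endian = "little")
  need <- 84 + nf * 50
  if (sz < need)
    stop("truncated binary STL: expected ", need, " bytes for ", nf,
         " facets, file ends at byte ", sz)
  tri <- matrix(0, nf * 3L, 3L)
  for (i in seq_len(nf)) {
    vals <- readBin(con, "double", n = 12, size = 4, endian = "little")
    invisible(readBin(con, "raw", n = 2))
    tri[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  weldFacets(tri)
}

readPly <- function(path) {
  txt <- readLines(path, warn = FALSE)
  endh <- match("end_header", trimws(txt))
  if (is.na(endh)) stop("malformed PLY (no end_header) at byte offset ",
                        sum(nchar(txt, type = "bytes") + 1L), ": ", path)
  hdr <- trimws(txt[seq_len(endh)])
  if (!identical(hdr[1], "ply") || !any(grepl("format ascii", hdr)))
    stop("only ASCII PLY supported: ", path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  vidx <- grep("^element vertex", hdr)
  fidx <- grep("^element face", hdr)
  vprops <- hdr[seq(vidx + 1L, fidx - 1L)]
  vprops <- sub("^property \\S+ ", "", vprops[grepl("^property", vprops)])
  if (endh + nv + nf > length(txt))
    stop("truncated PLY: expected ", nv, " vertices and ", nf, " faces: ", path)
  vt <- t(vapply(strsplit(trimws(txt[endh + seq_len(nv)]), "\\s+"),
                 as.numeric, numeric(length(vprops))))
  fc <- t(vapply(strsplit(trimws(txt[endh + nv + seq_len(nf)]), "\\s+"),
                 as.numeric, numeric(4)))
  if (any(fc[, 1] != 3)) stop("non-triangular PLY faces not supported: ", path)
  sc <- if ("deviation_mm" %in% vprops)
    vt[, match("deviation_mm", vprops)] else NULL
  TriMesh(vt[, match(c("x", "y", "z"), vprops), drop = FALSE],
          fc[, 2:4, drop = FALSE] + 1L, vertexScalar = sc)
}
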