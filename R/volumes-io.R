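# Volume input/output: NIfTI via RNifti, plus a minimal reader for axial
# DICOM series (explicit or implicit VR, little endian).  Oblique series are
# rejected: every downstream step assumes grid-aligned axial planes.

#' Read a CT volume
#'
#' Reads either a NIfTI file or a directory holding one axial DICOM series.
#' Stored values are returned as Hounsfield units (DICOM rescale slope and
#' intercept are applied; NIfTI scaling is applied by the reader).  Spacing
#' and origin are in millimetres, voxel-centre convention.
#'
#' @param path a `.nii`/`.nii.gz` file or a directory of DICOM slices.
#' @param format `"auto"` (default, decided from `path`), `"nifti"` or
#'   `"dicom"`.
#' @return A [CTVolume-class].
#' @details DICOM series must have uniform slice spacing (1% tolerance) and
#'   identity direction cosines; a missing or displaced slice aborts with an
#'   error naming the first inconsistent slice.
#' @export
readVolume <- function(path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom" else "nifti"
  if (format == "nifti") readVolumeNifti(path) else readVolumeDicom(path)
}

readVolumeNifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[seq_len(3)]
  xf <- RNifti::xform(img)
  R <- xf[1:3, 1:3]
  Rn <- sweep(abs(R), 2, pmax(sqrt(colSums(R^2)), 1e-12), `/`)
  if (max(abs(Rn - diag(3))) > 0.01)
    stop("oblique NIfTI orientation not supported (direction cosines must be grid-aligned)")
  origin <- as.numeric(xf[1:3, 4])
  if (all(xf[1:3, 1:3] == diag(3)) && all(origin == 0)) origin <- c(0, 0, 0)
  CTVolume(arr, spacing = sp, origin = origin)
}

#' Write a CT volume as NIfTI
#'
#' @param volume a [CTVolume-class].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@data)
  RNifti::pixdim(img) <- volume@spacing
  m <- diag(4)
  m[1:3, 1:3] <- diag(volume@spacing)
  m[1:3, 4] <- volume@origin
  m <- structure(m, code = 2L)
  img <- RNifti::`sform<-`(img, m)
  img <- RNifti::`qform<-`(img, m)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- DICOM ----------------------------------------------------------------

# Parse one little-endian DICOM file and return the handful of tags the
# volume assembly needs.  VR handling: explicit VR detected per element;
# elements with unrecognised VR bytes fall back to implicit VR.
parseDicomFile <- function(file) {
  raw <- readBin(file, "raw", n = file.info(file)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", file)
  pos <- 133L
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) as.numeric(u16(at)) + 65536 * as.numeric(u16(at + 2L))
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  want <- c("0020,0032", "0020,0037", "0028,0010", "0028,0011",
            "0028,0030", "0028,0100", "0028,0103", "0028,1052",
            "0028,1053", "7fe0,0010")
  n <- length(raw)
  while (pos + 8L <= n) {
    grp <- u16(pos); ele <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    explicit <- grepl("^[A-Z]{2}$", vr)
    if (explicit && vr %in% long_vrs) {
      len <- u32(pos + 8L); hdr <- 12L
    } else if (explicit) {
      len <- as.numeric(u16(pos + 6L)); hdr <- 8L
    } else {
      len <- u32(pos + 4L); hdr <- 8L
    }
    key <- sprintf("%04x,%04x", grp, ele)
    if (len > n - pos - hdr + 1L)
      stop("truncated DICOM element ", key, " in ", file)
    if (key %in% want) {
      body <- raw[(pos + hdr):(pos + hdr + len - 1L)]
      tags[[key]] <- body
    }
    pos <- pos + hdr + as.integer(len)
  }
  ds <- function(key, default = NULL) {
    if (is.null(tags[[key]])) return(default)
    as.numeric(strsplit(trimws(rawToChar(tags[[key]])), "\\\\")[[1]])
  }
  us <- function(key, default = NULL) {
    if (is.null(tags[[key]])) return(default)
    as.integer(tags[[key]][1]) + 256L * as.integer(tags[[key]][2])
  }
  rows <- us("0028,0010"); cols <- us("0028,0011")
  bits <- us("0028,0100", 16L); pixrep <- us("0028,0103", 0L)
  if (is.null(rows) || is.null(cols) || is.null(tags[["7fe0,0010"]]))
    stop("DICOM file lacks image data: ", file)
  if (bits != 16L) stop("only 16-bit DICOM pixel data supported: ", file)
  px <- readBin(tags[["7fe0,0010"]], "integer", n = rows * cols, size = 2L,
                signed = pixrep == 1L, endian = "little")
  list(position = ds("0020,0032", c(0, 0, 0)),
       orientation = ds("0020,0037", c(1, 0, 0, 0, 1, 0)),
       rows = rows, cols = cols,
       pixel_spacing = ds("0028,0030", c(1, 1)),
       slope = ds("0028,1053", 1)[1],
       intercept = ds("0028,1052", 0)[1],
       # row-major storage: columns vary fastest -> index = column + row*cols
       pixels = matrix(px, nrow = cols, ncol = rows))
}

readVolumeDicom <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2L) stop("DICOM series needs at least 2 slices: ", path)
  slices <- lapply(files, parseDicomFile)
  for (s in slices)
    if (max(abs(s$orientation - c(1, 0, 0, 0, 1, 0))) > 1e-6)
      stop("oblique DICOM series rejected: direction cosines are not axial identity")
  z <- vapply(slices, function(s) s$position[3], 0)
  ord <- order(z)
  slices <- slices[ord]; files <- files[ord]; z <- z[ord]
  dz <- diff(z)
  if (any(dz <= 0)) stop("duplicate slice positions in DICOM series")
  med <- median(dz)
  bad <- which(abs(dz - med) > 0.01 * med)
  if (length(bad) > 0)
    stop(sprintf(paste0("inconsistent DICOM slice spacing: gap of %.4f mm ",
                        "(expected %.4f) after slice %d (%s)"),
                 dz[bad[1]], med, bad[1], basename(files[bad[1]])))
  dims <- c(slices[[1]]$cols, slices[[1]]$rows)
  for (s in slices)
    if (s$cols != dims[1] || s$rows != dims[2])
      stop("DICOM slices have mismatched matrix sizes")
  ps <- slices[[1]]$pixel_spacing # (row spacing = y, column spacing = x)
  arr <- array(0, dim = c(dims[1], dims[2], length(slices)))
  for (k in seq_along(slices))
    arr[, , k] <- slices[[k]]$slope * slices[[k]]$pixels +
      slices[[k]]$intercept
  CTVolume(arr, spacing = c(ps[2], ps[1], med),
           origin = slices[[1]]$position)
}
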