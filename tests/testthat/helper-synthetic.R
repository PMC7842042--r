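# Shared synthetic fixtures, all generated in code at test time.

# Write a minimal explicit-VR little-endian DICOM slice (16-bit pixels).
writeDicomSlice <- function(path, pixels, position, pixel_spacing = c(1, 1),
                            slope = 1, intercept = 0,
                            orientation = c(1, 0, 0, 0, 1, 0)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  elem_str <- function(grp, ele, vr, value) {
    body <- charToRaw(value)
    if (length(body) %% 2 == 1) body <- c(body, charToRaw(" "))
    u16(grp); u16(ele)
    writeBin(charToRaw(vr), con)
    u16(length(body))
    writeBin(body, con)
  }
  elem_us <- function(grp, ele, value) {
    u16(grp); u16(ele)
    writeBin(charToRaw("US"), con)
    u16(2L)
    u16(value)
  }
  ds <- function(v) paste(format(v, trim = TRUE), collapse = "\\")
  elem_str(0x0020L, 0x0032L, "DS", ds(position))
  elem_str(0x0020L, 0x0037L, "DS", ds(orientation))
  elem_us(0x0028L, 0x0010L, nrow(pixels))  # Rows
  elem_us(0x0028L, 0x0011L, ncol(pixels))  # Columns
  elem_str(0x0028L, 0x0030L, "DS", ds(pixel_spacing))
  elem_us(0x0028L, 0x0100L, 16L)           # BitsAllocated
  elem_us(0x0028L, 0x0103L, 0L)            # PixelRepresentation (unsigned)
  elem_str(0x0028L, 0x1052L, "DS", ds(intercept))
  elem_str(0x0028L, 0x1053L, "DS", ds(slope))
  px <- as.integer(t(pixels))              # row-major, columns fastest
  u16(0x7fe0L); u16(0x0010L)
  writeBin(charToRaw("OW"), con)
  u16(0L)
  writeBin(length(px) * 2L, con, size = 4, endian = "little")
  writeBin(px, con, size = 2, endian = "little")
  invisible(path)
}

writeDicomSeries <- function(dir, nslices = 4, rows = 6, cols = 5,
                             dz = 0.3, skip = integer(),
                             pixel_spacing = c(0.25, 0.2),
                             slope = 1, intercept = -1024,
                             orientation = c(1, 0, 0, 0, 1, 0),
                             value = 1274L) {
  dir.create(dir, showWarnings = FALSE)
  for (k in setdiff(seq_len(nslices), skip)) {
    px <- matrix(value + k, rows, cols)
    writeDicomSlice(file.path(dir, sprintf("slice%03d.dcm", k)), px,
                    position = c(0, 0, (k - 1) * dz),
                    pixel_spacing = pixel_spacing,
                    slope = slope, intercept = intercept,
                    orientation = orientation)
  }
  dir
}

# Rasterised sphere mask of radius r (mm) at isotropic spacing.
sphereMask <- function(r = 10, spacing = 0.2, margin = 1) {
  half <- r + margin
  g <- seq(-half, half, by = spacing)
  n <- length(g)
  arr <- array(FALSE, c(n, n, n))
  r2xy <- outer(g^2, g^2, `+`)
  for (k in seq_len(n)) arr[, , k] <- r2xy + g[k]^2 <= r^2
  BinaryMask(arr, spacing = rep(spacing, 3), origin = rep(g[1], 3))
}

# Circular head contour of radius R with an inward articular recession of
# depth t over the azimuth sector [a1, a2] (degrees), n points.
recessedContour <- function(R = 10, t = 1, a1 = -30, a2 = 30, n = 360,
                            z = 0) {
  ang <- (seq_len(n) - 1) / n * 360
  inside <- ((ang - a1) %% 360) <= ((a2 - a1) %% 360)
  r <- ifelse(inside, R - t, R)
  SliceContour(cbind(r * cos(ang * pi / 180), r * sin(ang * pi / 180)),
               z = z, boneLabel = "radius")
}

# Circular head cylinder (radius R, recessed by t over the ulna-facing
# sector) apposed to an ulnar block whose subchondral wall sits at
# R + t + fluid + t_notch from the head axis.
makeJointMasks <- function(R = 8, t = 1, fluid = 0, t_notch = t,
                           spacing = 0.2, nz = 5, sector = c(-45, 45)) {
  xg <- seq(-R - 2, R + t + fluid + t_notch + 6, by = spacing)
  yg <- seq(-R - 2, R + 2, by = spacing)
  X <- matrix(xg, length(xg), length(yg))
  Y <- matrix(yg, length(xg), length(yg), byrow = TRUE)
  az <- (atan2(Y, X) * 180 / pi) %% 360
  inSector <- ((az - sector[1]) %% 360) <= ((sector[2] - sector[1]) %% 360)
  rho <- sqrt(X^2 + Y^2)
  head2d <- rho <= ifelse(inSector, R, R + t)
  wall <- R + t + fluid + t_notch
  ulna2d <- X >= 0 & abs(az - ifelse(az > 180, 360, 0)) <= 45 &
    rho >= wall & rho <= wall + 4
  mk <- function(sl) BinaryMask(array(sl, c(dim(sl), nz)),
                                spacing = c(spacing, spacing, 1),
                                origin = c(xg[1], yg[1], 0))
  list(head = mk(head2d), ulna = mk(ulna2d))
}

# Flat-topped head slab with a capitellar slab above, axis-aligned;
# subchondral gap = gap_vox * sz.
makeCapitellarMasks <- function(gap_vox, sz = 0.5, nxy = 20, ktop = 10,
                                nz = 24) {
  head <- array(FALSE, c(nxy, nxy, nz))
  head[3:(nxy - 2), 3:(nxy - 2), 1:ktop] <- TRUE
  cap <- array(FALSE, c(nxy, nxy, nz))
  kc <- ktop + gap_vox + 1L
  cap[3:(nxy - 2), 3:(nxy - 2), kc:min(nz, kc + 4L)] <- TRUE
  list(head = BinaryMask(head, c(sz, sz, sz), c(0, 0, 0)),
       cap = BinaryMask(cap, c(sz, sz, sz), c(0, 0, 0)))
}

# Memoised heavy default-phantom pipeline shared by the acceptance tests.
.cache <- new.env(parent = emptyenv())
defaultPhantomRun <- function() {
  if (!is.null(.cache$run)) return(.cache$run)
  spec <- phantomSpec() # symmetric 1 mm cartilage, no fluid, 0.2/0.2/0.3 mm
  vol <- rasterizePhantom(spec)
  truth <- buildTruth(spec)
  cir <- runCIRM(vol, truth$truth_landmarks$seed_points)
  .cache$run <- list(spec = spec, vol = vol, truth = truth, cir = cir)
  .cache$run
}
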