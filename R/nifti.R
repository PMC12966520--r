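# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only the subset of the standard that CTA volumes and label maps need is
# implemented: 3D grids, datatypes uint8/int8/int16/uint16/int32/float32/
# float64, scl_slope/scl_inter rescaling, pixdim spacing, and an
# axis-aligned sform. Non-axis-aligned affines are rejected rather than
# silently reoriented.

NIFTI_DT <- c(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
              float64 = 64L, int8 = 256L, uint16 = 512L)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

nifti_read_raw <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr_bytes <- readBin(con, "raw", 348)
  if (length(hdr_bytes) < 348) stop("not a NIfTI file (truncated header): ", path)
  endian <- "little"
  sz <- readBin(hdr_bytes[1:4], "integer", 1, 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_bytes[1:4], "integer", 1, 4, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  magic <- rawToChar(hdr_bytes[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) is not supported: ", path)

  rd <- function(off, what, n, size) {
    readBin(hdr_bytes[(off + 1):(off + n * size)], what, n, size,
            signed = TRUE, endian = endian)
  }
  dims <- rd(40, "integer", 8, 2)
  ndim <- dims[1]
  if (ndim < 3) stop("expected a 3D volume, got ", ndim, "D: ", path)
  d <- dims[2:4]
  extra <- if (ndim > 3) prod(pmax(dims[5:(1 + ndim)], 1L)) else 1L
  if (extra != 1L) stop("expected a single 3D volume, file has ", extra, " frames")
  datatype <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "numeric", 8, 4)
  vox_offset <- rd(108, "numeric", 1, 4)
  scl_slope <- rd(112, "numeric", 1, 4)
  scl_inter <- rd(116, "numeric", 1, 4)
  sform_code <- rd(254, "integer", 1, 2)
  srow <- matrix(rd(280, "numeric", 12, 4), nrow = 3, byrow = TRUE)

  spacing <- abs(pixdim[2:4])
  origin <- c(0, 0, 0)
  if (sform_code > 0) {
    rot <- srow[, 1:3]
    colnorm <- sqrt(colSums(rot^2))
    offdiag <- abs(rot) - diag(colnorm)
    if (max(abs(offdiag)) > 1e-4 * max(colnorm))
      stop("non-axis-aligned affine is not supported: ", path)
    spacing <- colnorm
    origin <- srow[, 4]
  }
  if (any(spacing <= 0)) stop("non-positive voxel spacing in header: ", path)

  n <- prod(d)
  skip <- round(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  data <- switch(as.character(datatype),
    "2"   = readBin(con, "integer", n, 1, signed = FALSE, endian = endian),
    "256" = readBin(con, "integer", n, 1, signed = TRUE, endian = endian),
    "4"   = readBin(con, "integer", n, 2, signed = TRUE, endian = endian),
    "512" = readBin(con, "integer", n, 2, signed = FALSE, endian = endian),
    "8"   = readBin(con, "integer", n, 4, endian = endian),
    "16"  = readBin(con, "numeric", n, 4, endian = endian),
    "64"  = readBin(con, "numeric", n, 8, endian = endian),
    stop("unsupported NIfTI datatype code ", datatype, ": ", path))
  if (length(data) < n) stop("truncated NIfTI data section: ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(grid = array(data, d), spacing = spacing, origin = origin,
       datatype = datatype)
}

nifti_write_raw <- function(grid, spacing, origin, path, datatype) {
  d <- dim(grid)
  stopifnot(length(d) == 3)
  dtcode <- NIFTI_DT[[datatype]]
  bitpix <- c(uint8 = 8L, int16 = 16L, int32 = 32L, float32 = 32L,
              float64 = 64L, int8 = 8L, uint16 = 16L)[[datatype]]
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")

  w(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                       # data_type..dim_info (unused)
  w(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), 2)   # dim[8]
  w(numeric(3), 4)                             # intent_p1..p3
  w(0L, 2)                                     # intent_code
  w(as.integer(dtcode), 2)                     # datatype
  w(as.integer(bitpix), 2)                     # bitpix
  w(0L, 2)                                     # slice_start
  w(c(1, spacing, 1, 1, 1, 1), 4)              # pixdim[8]
  w(352, 4)                                    # vox_offset
  w(c(1, 0), 4)                                # scl_slope, scl_inter
  w(0L, 2)                                     # slice_end
  writeBin(as.raw(c(0L, 10L)), con)            # slice_code, xyzt_units (mm|s)
  w(numeric(4), 4)                             # cal_max..toffset
  w(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                      # descrip[80] + aux_file[24]
  w(c(0L, 1L), 2)                              # qform_code, sform_code
  w(numeric(6), 4)                             # quatern + qoffset
  w(c(spacing[1], 0, 0, origin[1]), 4)         # srow_x
  w(c(0, spacing[2], 0, origin[2]), 4)         # srow_y
  w(c(0, 0, spacing[3], origin[3]), 4)         # srow_z
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  writeBin(raw(4), con)                        # extension indicator

  v <- as.vector(grid)
  switch(datatype,
    uint8   = ,
    int8    = writeBin(as.integer(v), con, size = 1, endian = "little"),
    int16   = ,
    uint16  = writeBin(as.integer(v), con, size = 2, endian = "little"),
    int32   = writeBin(as.integer(v), con, size = 4, endian = "little"),
    float32 = writeBin(as.numeric(v), con, size = 4, endian = "little"),
    float64 = writeBin(as.numeric(v), con, size = 8, endian = "little"))
  invisible(path)
}

#' Read a NIfTI volume
#'
#' Reads a single-file NIfTI-1 volume (`.nii` or `.nii.gz`) into one of the
#' package's containers. With `kind = "auto"`, grids holding non-integer
#' values become [hu_volume()]; integer grids with values in 0..4 become
#' [artery_label_map()]. A binary calcification mask is indistinguishable
#' from an aorta-only label map by content, so request `kind = "calc"`
#' explicitly when reading one.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param kind One of `"auto"`, `"hu"`, `"arteries"`, `"calc"`.
#' @return A `hu_volume`, `artery_label_map` or `calc_mask`; grid values,
#'   spacing and origin as stored in the file (integer maps are never
#'   interpolated on read).
#' @export
read_volume <- function(path, kind = c("auto", "hu", "arteries", "calc")) {
  kind <- match.arg(kind)
  raw <- nifti_read_raw(path)
  g <- raw$grid
  if (kind == "auto") {
    intlike <- raw$datatype %in% c(2L, 4L, 8L, 256L, 512L) ||
      (max(abs(g - round(g))) == 0 && min(g) >= 0 && max(g) <= 4)
    kind <- if (intlike) "arteries" else "hu"
  }
  switch(kind,
    hu = hu_volume(g, raw$spacing, raw$origin),
    arteries = artery_label_map(round(g), raw$spacing, raw$origin),
    calc = calc_mask(round(g), raw$spacing, raw$origin))
}

#' Write a volume to NIfTI
#'
#' Label maps and masks are written as `uint8`, HU volumes as `float32`.
#' The spacing and origin are stored in both `pixdim` and an axis-aligned
#' sform. Compression follows the file extension.
#'
#' @param vol A `hu_volume`, `artery_label_map` or `calc_mask`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  dt <- if (inherits(vol, "hu_volume")) "float32" else "uint8"
  nifti_write_raw(vol$grid, vol$spacing, vol$origin, path, dt)
  invisible(path)
}
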