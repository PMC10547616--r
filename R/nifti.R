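# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Deliberately small: enough of the standard to round-trip 3D scalar volumes
# (PET SUV grids, integer label maps) with voxel spacing and an sform affine.
# Scaling (scl_slope/scl_inter) is applied on read; data are written unscaled.
# Both endiannesses are read; output is always little-endian.

.nifti_dt <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`   = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`   = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16`  = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64`  = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L),
  `256` = list(what = "integer", size = 1L, signed = TRUE,  bitpix = 8L),
  `512` = list(what = "integer", size = 2L, signed = FALSE, bitpix = 16L)
)

#' Read a 3D NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) into an
#' array together with its voxel spacing (mm) and a 4x4 voxel-to-world affine.
#' The affine is taken from the sform when `sform_code > 0`, otherwise a
#' diagonal affine built from `pixdim` is used. `scl_slope`/`scl_inter`
#' rescaling is applied when present.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a list with elements `data` (3D array), `spacing` (numeric length 3,
#'   mm), `affine` (4x4 matrix) and `datatype` (NIfTI datatype code).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))

  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", n = 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    if (.swap_int32(sizeof_hdr) != 348L)
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  readBin(con, "raw", n = 36L)                       # unused header fields
  dim_ <- readBin(con, "integer", n = 8L, size = 2L, endian = endian)
  readBin(con, "raw", n = 14L)                       # intent params + codes
  datatype <- readBin(con, "integer", n = 1L, size = 2L, endian = endian)
  bitpix   <- readBin(con, "integer", n = 1L, size = 2L, endian = endian)
  readBin(con, "raw", n = 2L)                        # slice_start
  pixdim <- readBin(con, "numeric", n = 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "numeric", n = 1L, size = 4L, endian = endian)
  scl_slope  <- readBin(con, "numeric", n = 1L, size = 4L, endian = endian)
  scl_inter  <- readBin(con, "numeric", n = 1L, size = 4L, endian = endian)
  readBin(con, "raw", n = 120L)                      # through intent_name
  qform_code <- readBin(con, "integer", n = 1L, size = 2L, endian = endian)
  sform_code <- readBin(con, "integer", n = 1L, size = 2L, endian = endian)
  readBin(con, "numeric", n = 6L, size = 4L, endian = endian)  # quaternions
  srow <- matrix(readBin(con, "numeric", n = 12L, size = 4L, endian = endian),
                 nrow = 3L, byrow = TRUE)
  readBin(con, "raw", n = 16L)                       # intent_name
  magic <- rawToChar(readBin(con, "raw", n = 4L))
  if (!startsWith(magic, "n+1") && !startsWith(magic, "ni1"))
    stop("bad NIfTI magic string in ", path)

  ndim <- dim_[1L]
  if (ndim < 3L) stop("expected a 3D volume, got ", ndim, "D: ", path)
  shape <- dim_[2:(ndim + 1L)]
  if (ndim > 3L) {
    if (any(shape[4:length(shape)] > 1L))
      stop("expected a 3D volume, got non-singleton dimension ", ndim, "D: ", path)
    shape <- shape[1:3]
  }

  spec <- .nifti_dt[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code: ", datatype)

  # skip any header extension up to vox_offset (we have consumed 348 bytes)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)

  n <- prod(shape)
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  spacing <- abs(pixdim[2:4])
  affine <- if (sform_code > 0L) rbind(srow, c(0, 0, 0, 1)) else
    diag(c(spacing, 1))
  list(data = array(vals, dim = shape), spacing = spacing,
       affine = affine, datatype = datatype)
}

#' Write a 3D array as a NIfTI-1 file
#'
#' @param data 3D numeric or integer array.
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @param spacing voxel edge lengths in mm (length 3).
#' @param affine optional 4x4 voxel-to-world affine stored as the sform;
#'   defaults to `diag(c(spacing, 1))`.
#' @param datatype NIfTI datatype code: 16 (float32, default), 64 (float64),
#'   8 (int32), 4 (int16) or 2 (uint8).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), affine = NULL,
                        datatype = 16L) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L, all(spacing > 0))
  spec <- .nifti_dt[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code: ", datatype)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  stopifnot(all(dim(affine) == c(4L, 4L)))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  end <- "little"
  w_i4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = end)
  w_i2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = end)
  w_f4 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = end)
  w_raw <- function(n) writeBin(raw(n), con)

  w_i4(348L)                                  # sizeof_hdr
  w_raw(36L)
  w_i2(c(3L, dim(data), 1L, 1L, 1L, 1L))      # dim[8]
  w_raw(14L)
  w_i2(datatype); w_i2(spec$bitpix); w_raw(2L)
  w_f4(c(1, spacing, 1, 1, 1, 1))             # pixdim[8]
  w_f4(352)                                   # vox_offset
  w_f4(1); w_f4(0)                            # scl_slope, scl_inter
  w_raw(120L)
  w_i2(0L); w_i2(1L)                          # qform_code = 0, sform_code = 1
  w_f4(numeric(6L))                           # quaternion block
  w_f4(as.numeric(t(affine[1:3, ])))          # srow_x, srow_y, srow_z
  w_raw(16L)                                  # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  w_raw(4L)                                   # pad to vox_offset 352

  vals <- as.vector(data)
  if (spec$what == "integer") {
    vals <- as.integer(round(vals))
    writeBin(vals, con, size = spec$size, endian = end)
  } else {
    writeBin(as.numeric(vals), con, size = spec$size, endian = end)
  }
  invisible(path)
}

.swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  readBin(rev(b), "integer", size = 4L, endian = "little")
}
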