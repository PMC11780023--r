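#' Read a NIfTI-1 volume
#'
#' A minimal self-contained NIfTI-1 reader (no R NIfTI package is assumed).
#' Handles `.nii` and `.nii.gz`, both endiannesses, the common datatypes
#' (uint8, int16, int32, float32, float64, int8, uint16), and applies
#' `scl_slope`/`scl_inter` when set.  Spacing is taken from `pixdim`,
#' the origin from the sform translation (or qoffset as fallback).
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return A [volume].
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("not a NIfTI-1 file (short header): ", path)
  rd <- function(what, n, off, size, endian) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = !(what == "integer" && size == 1))
  }
  endian <- "little"
  if (rd("integer", 1, 0, 4, endian) != 348L) {
    endian <- "big"
    if (rd("integer", 1, 0, 4, endian) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic: ", magic)
  dimv <- rd("integer", 8, 40, 2, endian)
  ndim <- dimv[1]
  if (ndim < 3) stop("expected a 3-D volume, got ", ndim, " dims")
  d <- pmax(dimv[2:4], 1L)
  nextra <- if (ndim > 3) prod(pmax(dimv[5:(1 + ndim)], 1L)) else 1
  if (nextra != 1) stop("only single-frame 3-D volumes are supported")
  datatype <- rd("integer", 1, 70, 2, endian)
  pixdim <- rd("numeric", 8, 76, 4, endian)
  vox_offset <- rd("numeric", 1, 108, 4, endian)
  scl_slope <- rd("numeric", 1, 112, 4, endian)
  scl_inter <- rd("numeric", 1, 116, 4, endian)
  sform_code <- rd("integer", 1, 254, 2, endian)
  srow <- matrix(rd("numeric", 12, 280, 4, endian), 3, 4, byrow = TRUE)
  qoffset <- rd("numeric", 3, 268, 4, endian)
  origin <- if (sform_code > 0) srow[, 4] else qoffset
  spacing <- abs(pixdim[2:4])
  if (any(spacing <= 0)) spacing[spacing <= 0] <- 1
  typeinfo <- switch(as.character(datatype),
    "2"   = list("integer", 1, FALSE),
    "4"   = list("integer", 2, TRUE),
    "8"   = list("integer", 4, TRUE),
    "16"  = list("numeric", 4, TRUE),
    "64"  = list("numeric", 8, TRUE),
    "256" = list("integer", 1, TRUE),
    "512" = list("integer", 2, FALSE),
    stop("unsupported NIfTI datatype code: ", datatype))
  n <- prod(d)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, typeinfo[[1]], n = n, size = typeinfo[[2]],
                  endian = endian, signed = typeinfo[[3]])
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0)
    vals <- vals * scl_slope + scl_inter
  volume(array(vals, dim = d), spacing_mm = spacing, origin_mm = origin)
}

#' Write a NIfTI-1 volume
#'
#' Writes little-endian single-file NIfTI-1 (`.nii`, gzipped when the path
#' ends in `.gz`).  Images are stored as float32, binary masks as uint8.
#' Spacing goes to `pixdim`, the origin to a diagonal sform.
#'
#' @param vol a [volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype `"auto"` (uint8 iff data are 0/1), `"float32"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = c("auto", "float32", "uint8")) {
  stopifnot(is_volume(vol))
  datatype <- match.arg(datatype)
  if (datatype == "auto")
    datatype <- if (all(vol$data %in% c(0, 1))) "uint8" else "float32"
  d <- dim(vol$data)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # unused
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)               # dim[8]
  writeBin(raw(14), con)                        # intent params etc.
  dt <- if (datatype == "uint8") c(2L, 8L) else c(16L, 32L)
  wi(dt, 2)                                     # datatype, bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(0, vol$spacing_mm, 1, 1, 1, 1))          # pixdim[8]
  wf(352)                                       # vox_offset
  wf(c(0, 0))                                   # scl_slope, scl_inter
  writeBin(raw(4), con)                         # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                                # cal_max, cal_min, slice_duration
  wf(0)                                         # toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                       # descrip + aux_file
  wi(c(0L, 1L), 2)                              # qform_code, sform_code
  wf(c(0, 0, 0))                                # quatern b, c, d
  wf(vol$origin_mm)                             # qoffset x, y, z
  wf(c(vol$spacing_mm[1], 0, 0, vol$origin_mm[1]))  # srow_x
  wf(c(0, vol$spacing_mm[2], 0, vol$origin_mm[2]))  # srow_y
  wf(c(0, 0, vol$spacing_mm[3], vol$origin_mm[3]))  # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  writeBin(raw(4), con)                         # extension flag
  if (datatype == "uint8") {
    wi(round(vol$data), 1)
  } else {
    wf(vol$data)
  }
  invisible(path)
}
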