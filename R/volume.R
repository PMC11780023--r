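#' Construct a 3-D image volume
#'
#' The basic carrier for all image math in the package: a 3-D numeric array
#' with voxel spacing and world origin, both in millimetres.  Masks are
#' volumes whose data are 0/1.
#'
#' @param data 3-D numeric array of finite values.
#' @param spacing_mm numeric(3), strictly positive voxel spacing in mm.
#' @param origin_mm numeric(3), world coordinate of the first voxel corner.
#' @return An object of class `volume`.
#' @export
volume <- function(data, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (!all(is.finite(data))) stop("volume data must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive reals")
  if (length(origin_mm) != 3L) stop("`origin_mm` must have length 3")
  structure(list(data = data, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %d x %d x %d voxels, spacing %s mm, range [%g, %g]\n",
              d[1], d[2], d[3],
              paste(format(x$spacing_mm), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "volume")

#' Coerce a volume to a binary mask
#'
#' Any nonzero voxel becomes 1.  Used when reading segmentations whose
#' foreground label is not literally 1.
#'
#' @param vol a `volume`.
#' @return A `volume` with 0/1 data.
#' @export
as_mask <- function(vol) {
  stopifnot(is_volume(vol))
  vol$data <- (vol$data != 0) * 1
  vol
}

# Internal consistency check between an image and its mask.
check_pair <- function(vol, mask) {
  if (!identical(dim(vol$data), dim(mask$data)))
    stop("image and mask grids differ in shape")
  if (max(abs(vol$spacing_mm - mask$spacing_mm)) > 1e-6)
    stop("image and mask spacings differ")
  invisible(TRUE)
}

mask_count <- function(mask) sum(mask$data != 0)
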