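#' Rescale intensities linearly to 0-255
#'
#' Maps the volume minimum to 0 and the maximum to 255, linearly in between.
#' Constant volumes map to all-zero (degenerate range; only reachable on
#' pathological inputs).
#'
#' @param vol a [volume].
#' @return A [volume] with values in `[0, 255]`.
#' @export
normalize_0_255 <- function(vol) {
  stopifnot(is_volume(vol))
  r <- range(vol$data)
  if (r[2] - r[1] <= 0) {
    vol$data[] <- 0
  } else {
    vol$data <- (vol$data - r[1]) / (r[2] - r[1]) * 255
  }
  vol
}

#' Histogram equalization
#'
#' Classical CDF-mapping equalization over `n_bins` bins spanning
#' `[0, 255]`.  The transform is monotone non-decreasing in the input and
#' its output range is contained in `[0, 255]`.  Constant volumes are
#' returned unchanged.
#'
#' @param vol a [volume] with values in `[0, 255]` (see [normalize_0_255]).
#' @param n_bins number of histogram bins (default 256, the 8-bit convention).
#' @return An equalized [volume].
#' @export
hist_equalize <- function(vol, n_bins = 256L) {
  stopifnot(is_volume(vol), n_bins >= 2)
  x <- vol$data
  if (min(x) < -1e-8 || max(x) > 255 + 1e-8)
    stop("hist_equalize expects values in [0, 255]; run normalize_0_255 first")
  bin <- pmin(floor(x / 255 * n_bins), n_bins - 1)   # 0-based bin index
  counts <- tabulate(bin + 1L, nbins = n_bins)
  cdf <- cumsum(counts) / length(x)
  cdf_min <- cdf[which(counts > 0)[1]]
  if (cdf_min >= 1) return(vol)                      # single occupied bin
  mapped <- 255 * (cdf - cdf_min) / (1 - cdf_min)
  vol$data <- array(mapped[bin + 1L], dim = dim(x))
  vol
}

#' Resample a volume to a target spacing
#'
#' Grid dimensions follow `round(old_dim * old_spacing / target)`.  Linear
#' interpolation is used for images and nearest-neighbour for masks (which
#' therefore stay binary); constant volumes remain exactly constant.
#'
#' @param vol a [volume].
#' @param target_mm numeric(3) target spacing in mm (default isotropic 1 mm).
#' @param interpolation `"linear"` (images) or `"nearest"` (masks).
#' @return The resampled [volume].
#' @export
resample_isotropic <- function(vol, target_mm = c(1, 1, 1),
                               interpolation = c("linear", "nearest")) {
  stopifnot(is_volume(vol))
  interpolation <- match.arg(interpolation)
  target_mm <- rep_len(as.numeric(target_mm), 3)
  if (any(target_mm <= 0)) stop("target spacing must be positive")
  d <- dim(vol$data)
  nd <- round(d * vol$spacing_mm / target_mm)
  if (any(nd < 1)) stop("resampling would produce an empty grid")
  out <- vol$data
  for (ax in 1:3) {
    W <- interp_matrix(d[ax], vol$spacing_mm[ax], nd[ax], target_mm[ax],
                       method = interpolation)
    out <- apply_axis_matrix(out, W, ax)
  }
  if (interpolation == "nearest") out <- round(out)
  volume(out, spacing_mm = target_mm, origin_mm = vol$origin_mm)
}

#' Discretize a volume of interest into gray levels
#'
#' Fixed-bin-width discretization restricted to a mask:
#' `level(x) = floor((x - min_in_mask) / bin_width) + 1`, 0 outside the
#' mask.  Invariant to adding a constant to the whole VOI.
#'
#' @param vol a [volume] (preprocessed).
#' @param mask a binary [volume] on the same grid.
#' @param bin_width positive bin width in intensity units (default 5).
#' @return An object of class `dvoi` with fields `levels` (integer array,
#'   0 outside the mask), `n_levels`, `bin_width`, `intensity_min`, and
#'   `spacing_mm`.
#' @export
discretize <- function(vol, mask, bin_width = 5) {
  stopifnot(is_volume(vol), is_volume(mask))
  check_pair(vol, mask)
  if (bin_width <= 0) stop("`bin_width` must be positive")
  inm <- mask$data != 0
  if (!any(inm)) stop("mask is empty")
  x <- vol$data[inm]
  lv <- as.integer(floor((x - min(x)) / bin_width) + 1)
  levels <- array(0L, dim = dim(vol$data))
  levels[inm] <- lv
  structure(list(levels = levels, n_levels = max(lv), bin_width = bin_width,
                 intensity_min = min(x), spacing_mm = vol$spacing_mm),
            class = "dvoi")
}

#' Build a discretized VOI directly from an integer level grid
#'
#' Mainly for tests and small worked examples: wraps an integer array
#' (0 outside the mask, `>= 1` inside) as a `dvoi` without touching
#' intensities.
#'
#' @param levels 3-D integer array (a matrix is promoted to one slice).
#' @param bin_width nominal bin width recorded in the object.
#' @param spacing_mm voxel spacing.
#' @return A `dvoi`.
#' @export
as_dvoi <- function(levels, bin_width = 1, spacing_mm = c(1, 1, 1)) {
  if (is.matrix(levels)) levels <- array(levels, dim = c(dim(levels), 1))
  stopifnot(is.array(levels), length(dim(levels)) == 3L)
  storage.mode(levels) <- "integer"
  if (any(levels < 0)) stop("levels must be >= 0")
  if (!any(levels > 0)) stop("mask is empty")
  structure(list(levels = levels, n_levels = max(levels),
                 bin_width = bin_width, intensity_min = 0,
                 spacing_mm = spacing_mm),
            class = "dvoi")
}

#' @export
print.dvoi <- function(x, ...) {
  cat(sprintf("<dvoi> %s grid, %d in-mask voxels, %d gray levels (bin width %g)\n",
              paste(dim(x$levels), collapse = "x"), sum(x$levels > 0),
              x$n_levels, x$bin_width))
  invisible(x)
}

#' Standard preprocessing chain for one case-phase
#'
#' Applies the fixed pipeline order: 0-255 normalization, histogram
#' equalization, isotropic resampling (linear for the image, nearest for the
#' mask).  Per-VOI discretization is done later by the feature extractor.
#'
#' @param vol a raw image [volume].
#' @param mask the paired binary mask, or `NULL`.
#' @param target_mm target spacing (default 1 mm isotropic).
#' @param n_bins equalization bins (default 256).
#' @return `list(vol = , mask = )` of preprocessed volumes.
#' @export
preprocess_volume <- function(vol, mask = NULL, target_mm = c(1, 1, 1),
                              n_bins = 256L) {
  if (!is.null(mask)) check_pair(vol, mask)
  v <- hist_equalize(normalize_0_255(vol), n_bins = n_bins)
  v <- resample_isotropic(v, target_mm, "linear")
  m <- if (!is.null(mask)) {
    m2 <- resample_isotropic(mask, target_mm, "nearest")
    m2$data <- (m2$data != 0) * 1
    m2
  }
  list(vol = v, mask = m)
}
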