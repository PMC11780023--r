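#' Default derived-image filter set
#'
#' The 18 derived image types whose 93 intensity/texture features each, plus
#' the 107 original-image features, give the package's default 1781-feature
#' vector per phase: one-level stationary Haar wavelet (8 sub-bands),
#' Laplacian of Gaussian at sigma 2, 3, 4 and 5 mm, and the square,
#' square-root, logarithm, exponential, gradient-magnitude and 2-D
#' local-binary-pattern intensity transforms.
#'
#' @param wavelet logical, include the 8 Haar sub-bands.
#' @param log_sigmas_mm LoG scales in mm (`NULL` for none).
#' @param intensity logical, include square/squareroot/logarithm/exponential.
#' @param gradient,lbp2d logicals.
#' @return A list of filter specs understood by [apply_filter].
#' @export
default_filters <- function(wavelet = TRUE,
                            log_sigmas_mm = c(2, 3, 4, 5),
                            intensity = TRUE, gradient = TRUE, lbp2d = TRUE) {
  specs <- list()
  if (wavelet) specs <- c(specs, list(list(kind = "wavelet")))
  if (length(log_sigmas_mm))
    specs <- c(specs, list(list(kind = "log", sigmas_mm = log_sigmas_mm)))
  if (intensity)
    specs <- c(specs, lapply(c("square", "squareroot", "logarithm",
                               "exponential"), function(k) list(kind = k)))
  if (gradient) specs <- c(specs, list(list(kind = "gradient")))
  if (lbp2d) specs <- c(specs, list(list(kind = "lbp2d")))
  specs
}

#' Apply one image filter
#'
#' Produces the labelled derived images for a filter spec:
#' \describe{
#'   \item{wavelet}{one-level stationary (undecimated) separable Haar
#'     decomposition; exactly 8 sub-bands `LLL` ... `HHH` at the input shape.}
#'   \item{log}{Laplacian of Gaussian, one image per `sigmas_mm` entry
#'     (sigma interpreted in mm via the voxel spacing).}
#'   \item{square, squareroot, logarithm, exponential}{pointwise transforms
#'     of the 0-255 intensity range, rescaled back into 0-255.}
#'   \item{gradient}{spacing-aware central-difference gradient magnitude.}
#'   \item{lbp2d}{per-axial-slice 8-neighbour local binary pattern codes.}
#' }
#'
#' @param vol a preprocessed [volume] (values in 0-255 for the intensity
#'   transforms).
#' @param spec a list with `$kind` and parameters (see [default_filters]).
#' @return Named list of derived [volume]s.
#' @export
apply_filter <- function(vol, spec) {
  stopifnot(is_volume(vol))
  kind <- spec$kind
  switch(kind,
    wavelet = wavelet_bank(vol),
    log = {
      sig <- spec$sigmas_mm
      if (is.null(sig)) sig <- c(2, 3, 4, 5)
      if (any(sig <= 0)) stop("LoG sigmas must be positive")
      if (any(sig < min(vol$spacing_mm) / 2))
        warning("LoG sigma smaller than half the voxel spacing")
      out <- lapply(sig, function(s) log_filter(vol, s))
      names(out) <- sprintf("log-sigma-%.1f", sig)
      out
    },
    square = named_one(vol, "square", function(x) x^2 / 255),
    squareroot = named_one(vol, "squareroot", function(x) sqrt(255 * pmax(x, 0))),
    logarithm = named_one(vol, "logarithm",
                          function(x) 255 * log1p(pmax(x, 0)) / log1p(255)),
    exponential = named_one(vol, "exponential",
                            function(x) expm1(pmax(x, 0) / 255 * log(256))),
    gradient = {
      out <- vol; out$data <- gradient_magnitude(vol$data, vol$spacing_mm)
      stats::setNames(list(out), "gradient")
    },
    lbp2d = {
      out <- vol; out$data <- lbp2d_codes(vol$data)
      stats::setNames(list(out), "lbp2d")
    },
    stop("unknown filter kind: ", kind))
}

named_one <- function(vol, label, f) {
  out <- vol
  out$data <- f(vol$data)
  stats::setNames(list(out), label)
}

# One-level stationary Haar decomposition: all L/H kernel combinations over
# the three axes, sub-band label letter k = axis k.
wavelet_bank <- function(vol) {
  lo <- c(1, 1) / sqrt(2)
  hi <- c(1, -1) / sqrt(2)
  labels <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  out <- lapply(labels, function(lab) {
    a <- vol$data
    for (ax in 1:3) {
      k <- if (substr(lab, ax, ax) == "L") lo else hi
      a <- convolve_axis(a, k, ax)
    }
    v <- vol; v$data <- a; v
  })
  stats::setNames(out, paste0("wavelet-", labels))
}

# Laplacian of Gaussian with sigma in mm: sum over axes of the separable
# second-derivative-of-Gaussian kernel times plain Gaussians on the others.
log_filter <- function(vol, sigma_mm) {
  sp <- vol$spacing_mm
  kernels_g <- list(); kernels_gxx <- list()
  for (ax in 1:3) {
    s <- sigma_mm / sp[ax]                    # sigma in voxels on this axis
    r <- max(2L, ceiling(4 * s))
    x <- seq(-r, r)
    g <- exp(-x^2 / (2 * s^2))
    g <- g / sum(g)
    gxx <- ((x^2 - s^2) / s^4) * g            # d2/dx2 of Gaussian (voxel units)
    gxx <- (gxx - mean(gxx)) / sp[ax]^2       # zero-sum; back to mm^-2
    kernels_g[[ax]] <- g
    kernels_gxx[[ax]] <- gxx
  }
  acc <- NULL
  for (ax in 1:3) {
    a <- vol$data
    for (ax2 in 1:3) {
      k <- if (ax2 == ax) kernels_gxx[[ax2]] else kernels_g[[ax2]]
      a <- convolve_axis(a, k, ax2)
    }
    acc <- if (is.null(acc)) a else acc + a
  }
  out <- vol
  out$data <- sigma_mm^2 * acc                # scale-normalized response
  out
}

gradient_magnitude <- function(a, spacing) {
  d <- dim(a)
  acc <- array(0, d)
  for (ax in 1:3) {
    if (d[ax] < 2) next
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    n <- dim(ap)[1]
    up <- ap[c(2:n, n), , , drop = FALSE]     # replicate border
    dn <- ap[c(1, 1:(n - 1)), , , drop = FALSE]
    den <- rep(2 * spacing[ax], n); den[c(1, n)] <- spacing[ax]
    g <- (up - dn) / den
    acc <- acc + aperm(g, order(perm))^2
  }
  sqrt(acc)
}

# Basic (non-interpolated) 8-neighbour LBP per axial slice, replicate
# borders; codes in 0..255 treated downstream as an intensity image.
lbp2d_codes <- function(a) {
  d <- dim(a)
  out <- array(0, d)
  offs <- cbind(c(-1, -1, -1, 0, 1, 1, 1, 0), c(-1, 0, 1, 1, 1, 0, -1, -1))
  ri <- seq_len(d[1]); ci <- seq_len(d[2])
  for (z in seq_len(d[3])) {
    sl <- a[, , z]
    code <- matrix(0, d[1], d[2])
    for (k in 1:8) {
      rs <- pmin(pmax(ri + offs[k, 1], 1L), d[1])
      cs <- pmin(pmax(ci + offs[k, 2], 1L), d[2])
      code <- code + 2^(k - 1) * (sl[rs, cs] >= sl)
    }
    out[, , z] <- code
  }
  out
}

#' Build the full derived-image bank for feature extraction
#'
#' @param vol a preprocessed [volume].
#' @param filters list of filter specs (default [default_filters()]).
#' @return Named list of volumes, starting with `original`.
#' @export
filter_bank <- function(vol, filters = default_filters()) {
  out <- list(original = vol)
  for (spec in filters) out <- c(out, apply_filter(vol, spec))
  out
}
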