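#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All stochastic operations in the
# package go through this so that cohorts, splits, folds and bootstraps are
# pure functions of their seed.
run_seeded <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic small integer hash of a string, for deriving sub-seeds.
# Kept well below 2^31 so set.seed never overflows.
str_seed <- function(s, base = 0L) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 1999999973
  as.integer((h + as.numeric(base)) %% 1999999973)
}

# 1-D convolution along one axis of a 3-D array with reflect padding.
# `kernel` is applied centred (even-length kernels are offset by half a
# sample, which is fine for the Haar pair used here).
convolve_axis <- function(a, kernel, axis) {
  d <- dim(a)
  stopifnot(length(d) == 3L, axis %in% 1:3)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  k <- length(kernel)
  pad <- k  # generous one-sided padding
  n <- nrow(m)
  idx_top <- pmin(pmax(seq(pad, 1), 1L), n)        # reflected indices
  idx_top <- pmin(abs(seq_len(pad) - pad) + 1L, n) # pad, pad-1, ..., 1 -> reflect
  top <- m[pmin(pad:1 + 0L, n), , drop = FALSE]
  bot <- m[pmax(n - (1:pad) + 1L, 1L), , drop = FALSE]
  mp <- rbind(top, m, bot)
  # stats::filter convolves column-wise in C
  out <- stats::filter(mp, kernel, method = "convolution", sides = 2)
  out <- out[pad + seq_len(n), , drop = FALSE]
  out <- array(as.numeric(out), dim = dp)
  aperm(out, order(perm))
}

# Dense 1-D linear/nearest interpolation matrix mapping an old sampling grid
# (n_old points, spacing s_old) onto a new one (n_new points, spacing s_new),
# both using the voxel-centre convention with a shared origin.
interp_matrix <- function(n_old, s_old, n_new, s_new,
                          method = c("linear", "nearest")) {
  method <- match.arg(method)
  # centre of new voxel i (0-based): (i + 0.5) * s_new ; map into old index
  f <- ((seq_len(n_new) - 0.5) * s_new) / s_old - 0.5
  f <- pmin(pmax(f, 0), n_old - 1)
  W <- matrix(0, n_new, n_old)
  if (method == "nearest") {
    j <- pmin(floor(f + 0.5), n_old - 1)
    W[cbind(seq_len(n_new), j + 1)] <- 1
  } else {
    j0 <- pmin(floor(f), n_old - 1)
    j1 <- pmin(j0 + 1, n_old - 1)
    w1 <- f - j0
    W[cbind(seq_len(n_new), j0 + 1)] <- W[cbind(seq_len(n_new), j0 + 1)] + (1 - w1)
    W[cbind(seq_len(n_new), j1 + 1)] <- W[cbind(seq_len(n_new), j1 + 1)] + w1
  }
  W
}

# Apply an interpolation matrix along one axis of a 3-D array.
apply_axis_matrix <- function(a, W, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- W %*% matrix(ap, nrow = dp[1])
  out <- array(m, dim = c(nrow(W), dp[2], dp[3]))
  aperm(out, order(perm))
}

# Separable Gaussian smoothing of a 3-D array; sigma in voxels per axis.
gauss_smooth <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    a <- convolve_axis(a, k, ax)
  }
  a
}

# Squared Euclidean distance transform (Felzenszwalb & Huttenlocher lower
# envelope), separable, anisotropic spacing.  `sites` is a logical array;
# the result is the squared distance (mm^2) from every voxel to the nearest
# TRUE voxel.  Used for signed distances in mask perturbation.
edt_squared <- function(sites, spacing = c(1, 1, 1)) {
  d <- dim(sites)
  INF <- 1e20
  g <- array(ifelse(sites, 0, INF), dim = d)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    gp <- aperm(g, perm)
    dp <- dim(gp)
    m <- matrix(gp, nrow = dp[1])
    s <- spacing[ax]
    n <- dp[1]
    x2 <- (seq_len(n) * s)^2
    x1 <- seq_len(n) * s
    for (col in seq_len(ncol(m))) {
      f <- m[, col]
      if (all(f >= INF) || all(f == 0)) next
      v <- integer(n); z <- numeric(n + 1)
      k <- 1L; v[1] <- 1L; z[1] <- -INF; z[2] <- INF
      for (q in 2:n) {
        repeat {
          p <- v[k]
          sden <- 2 * (x1[q] - x1[p])
          sq <- ((f[q] + x2[q]) - (f[p] + x2[p])) / sden
          if (sq <= z[k]) { k <- k - 1L; if (k == 0L) { k <- 1L; v[1] <- q; z[1] <- -INF; z[2] <- INF; break } }
          else { k <- k + 1L; v[k] <- q; z[k] <- sq; z[k + 1] <- INF; break }
        }
      }
      kk <- 1L
      out <- numeric(n)
      for (q in 1:n) {
        while (z[kk + 1] < x1[q]) kk <- kk + 1L
        p <- v[kk]
        out[q] <- (x1[q] - x1[p])^2 + f[p]
      }
      m[, col] <- out
    }
    g <- aperm(array(m, dim = dp), order(perm))
  }
  g
}
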