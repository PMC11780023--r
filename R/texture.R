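# Texture-matrix builders on a discretized VOI (class `dvoi`).
#
# All five families operate on the integer level grid (0 = outside mask)
# produced by discretize().  GLCM and GLRLM are computed per direction over
# the 13 unique 3-D offsets and their features averaged over directions;
# GLSZM, GLDM and NGTDM use the full 26-neighbourhood.

# The 13 unique 3-D direction offsets (one of each +/- pair), memoised.
.offset_cache <- new.env(parent = emptyenv())

offsets13 <- function() {
  if (is.null(.offset_cache$o13)) {
    out <- NULL
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      o <- c(dx, dy, dz)
      if (all(o == 0)) next
      if (is.null(out) || !any(apply(out, 1, function(r) all(r == -o))))
        out <- rbind(out, o)
    }
    .offset_cache$o13 <- unname(out)
  }
  .offset_cache$o13
}

offsets26 <- function() {
  o13 <- offsets13()
  rbind(o13, -o13)
}

# Index ranges such that both p and p+off are inside the grid.
offset_ranges <- function(d, off) {
  rng <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    r <- if (o >= 0) seq_len(max(d[ax] - o, 0L)) else
      if (d[ax] + o >= 1) seq(1 - o, d[ax]) else integer(0)
    if (!length(r)) return(NULL)
    rng[[ax]] <- r
  }
  rng
}

# Level pairs (a at p, b at p+off), in-mask only.
offset_pairs <- function(L, off) {
  d <- dim(L)
  rng <- offset_ranges(d, off)
  if (is.null(rng)) return(NULL)
  a <- L[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  b <- L[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3], drop = FALSE]
  k <- a > 0L & b > 0L
  if (!any(k)) return(NULL)
  cbind(a[k], b[k])
}

new_texture_matrix <- function(kind, values, meta) {
  structure(list(kind = kind, values = values, meta = meta),
            class = "texture_matrix")
}

#' @export
print.texture_matrix <- function(x, ...) {
  cat(sprintf("<texture_matrix> %s, %s\n", x$kind,
              paste(dim(x$values), collapse = " x ")))
  invisible(x)
}

#' Gray level co-occurrence matrix
#'
#' Counts co-occurring level pairs at the given distance over the requested
#' direction offsets (13 unique 3-D directions by default), in-mask pairs
#' only, symmetrized, and normalized to sum to 1 per direction.  Features are
#' averaged over directions downstream; `$values` holds the direction-average
#' for inspection, `$matrices` the per-direction normalized matrices.
#'
#' @param voi a `dvoi` from [discretize].
#' @param distance offset scaling (default 1).
#' @param symmetric count each ordered pair in both orders (default TRUE).
#' @param directions integer matrix of offsets, one per row (default all 13).
#' @return A `texture_matrix` of kind `"glcm"`.
#' @export
compute_glcm <- function(voi, distance = 1L, symmetric = TRUE,
                         directions = offsets13()) {
  stopifnot(inherits(voi, "dvoi"))
  L <- voi$levels
  if (!any(L > 0)) stop("empty mask")
  ng <- voi$n_levels
  mats <- list()
  for (i in seq_len(nrow(directions))) {
    off <- directions[i, ] * distance
    pr <- offset_pairs(L, off)
    if (is.null(pr)) next
    C <- matrix(tabulate((pr[, 2] - 1L) * ng + pr[, 1], nbins = ng * ng),
                ng, ng)
    if (symmetric) C <- C + t(C)
    s <- sum(C)
    if (s > 0) mats[[length(mats) + 1L]] <- C / s
  }
  if (!length(mats)) stop("no valid co-occurrence pairs (mask too small)")
  avg <- Reduce(`+`, mats) / length(mats)
  new_texture_matrix("glcm", avg,
                     list(matrices = mats, distance = distance,
                          symmetric = symmetric, n_directions = length(mats)))
}

#' Gray level run length matrix
#'
#' `R(i, j)` counts maximal runs of level `i` and length `j` along each
#' direction; one count matrix per direction (features are averaged over
#' directions).  Runs partition the in-mask voxels per direction, so
#' `sum_j j * R(i, j)` equals the in-mask voxel count.
#'
#' @inheritParams compute_glcm
#' @return A `texture_matrix` of kind `"glrlm"`; `$values` is the
#'   direction-sum count matrix, `$matrices` the per-direction matrices.
#' @export
compute_glrlm <- function(voi, directions = offsets13()) {
  stopifnot(inherits(voi, "dvoi"))
  L <- voi$levels
  if (!any(L > 0)) stop("empty mask")
  ng <- voi$n_levels
  d <- dim(L)
  mats <- list()
  for (i in seq_len(nrow(directions))) {
    off <- directions[i, ]
    # run starts: in-mask voxels whose predecessor along -off differs
    prev <- array(0L, d)
    rng <- offset_ranges(d, -off)
    if (!is.null(rng)) {
      prev[rng[[1]], rng[[2]], rng[[3]]] <-
        L[rng[[1]] - off[1], rng[[2]] - off[2], rng[[3]] - off[3]]
    }
    start <- L > 0L & prev != L
    if (!any(start)) next
    coord <- which(start, arr.ind = TRUE)
    vals <- L[start]
    len <- rep(1L, length(vals))
    active <- seq_along(vals)
    k <- 1L
    while (length(active)) {
      nxt <- coord[active, , drop = FALSE] +
        matrix(off * k, length(active), 3, byrow = TRUE)
      ok <- nxt[, 1] >= 1 & nxt[, 1] <= d[1] &
            nxt[, 2] >= 1 & nxt[, 2] <= d[2] &
            nxt[, 3] >= 1 & nxt[, 3] <= d[3]
      if (any(ok)) {
        same <- L[nxt[ok, , drop = FALSE]] == vals[active][ok]
        ok[ok] <- same
      }
      active <- active[ok]
      len[active] <- len[active] + 1L
      k <- k + 1L
    }
    nr <- max(len)
    R <- matrix(tabulate((len - 1L) * ng + vals, nbins = ng * nr), ng, nr)
    mats[[length(mats) + 1L]] <- R
  }
  # pad to common run-length dimension for the summary matrix
  nrmax <- max(vapply(mats, ncol, 1L))
  padded <- lapply(mats, function(m)
    cbind(m, matrix(0, nrow(m), nrmax - ncol(m))))
  new_texture_matrix("glrlm", Reduce(`+`, padded),
                     list(matrices = mats, n_directions = length(mats)))
}

#' Gray level size zone matrix
#'
#' `S(i, s)` counts 26-connected zones of equal level `i` and size `s`.
#' Zones partition the in-mask voxels: `sum s * S(i, s)` equals the voxel
#' count.
#'
#' @param voi a `dvoi`.
#' @return A `texture_matrix` of kind `"glszm"`; `$values` is `S`.
#' @export
compute_glszm <- function(voi) {
  stopifnot(inherits(voi, "dvoi"))
  L <- voi$levels
  if (!any(L > 0)) stop("empty mask")
  zones <- zone_sizes(L)
  ng <- voi$n_levels
  ns <- max(zones$size)
  S <- matrix(tabulate((zones$size - 1L) * ng + zones$level, nbins = ng * ns),
              ng, ns)
  new_texture_matrix("glszm", S, list(connectivity = 26L))
}

# Label 26-connected equal-level zones; returns one row per zone.
zone_sizes <- function(L) {
  d <- dim(L)
  inm <- which(L > 0L)
  vid <- array(0L, d)
  vid[inm] <- seq_along(inm)
  edges <- list()
  o13 <- offsets13()
  for (i in seq_len(nrow(o13))) {
    off <- o13[i, ]
    rng <- offset_ranges(d, off)
    if (is.null(rng)) next
    a <- L[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    b <- L[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3], drop = FALSE]
    ia <- vid[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    ib <- vid[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3], drop = FALSE]
    k <- a > 0L & b > 0L & a == b
    if (any(k)) edges[[length(edges) + 1L]] <- cbind(ia[k], ib[k])
  }
  g <- igraph::make_empty_graph(n = length(inm), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)
  lvl <- L[inm]
  data.frame(level = lvl[match(seq_len(comp$no), comp$membership)],
             size = as.integer(comp$csize))
}

#' Gray level dependence matrix
#'
#' For each in-mask voxel the dependence `d` is the number of in-mask
#' 26-neighbours whose level differs by at most `alpha`; `D(i, d)` counts
#' voxels of level `i` with dependence `d` (columns start at `d = 0`).
#' Every voxel is counted exactly once: `sum(D)` equals the voxel count.
#'
#' @param voi a `dvoi`.
#' @param alpha dependence threshold on the absolute level difference
#'   (default 0).
#' @return A `texture_matrix` of kind `"gldm"`; `$values` has `d = 0` in the
#'   first column.
#' @export
compute_gldm <- function(voi, alpha = 0L) {
  stopifnot(inherits(voi, "dvoi"), alpha >= 0)
  L <- voi$levels
  if (!any(L > 0)) stop("empty mask")
  d <- dim(L)
  dep <- array(0L, d)
  o26 <- offsets26()
  for (i in seq_len(nrow(o26))) {
    off <- o26[i, ]
    rng <- offset_ranges(d, off)
    if (is.null(rng)) next
    a <- L[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    b <- L[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3], drop = FALSE]
    k <- a > 0L & b > 0L & abs(a - b) <= alpha
    sub <- dep[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    sub[k] <- sub[k] + 1L
    dep[rng[[1]], rng[[2]], rng[[3]]] <- sub
  }
  inm <- L > 0L
  ng <- voi$n_levels
  nd <- max(dep[inm]) + 1L
  D <- matrix(tabulate(dep[inm] * ng + L[inm], nbins = ng * nd), ng, nd)
  new_texture_matrix("gldm", D, list(alpha = alpha, d_start = 0L))
}

#' Neighbouring gray tone difference matrix
#'
#' Per level `i`: `n_i` = number of in-mask voxels at that level, `p_i =
#' n_i / N`, and `s_i` = the summed absolute difference between `i` and the
#' mean level of each voxel's in-mask 26-neighbours (voxels with no in-mask
#' neighbour contribute 0).
#'
#' @param voi a `dvoi`.
#' @return A `texture_matrix` of kind `"ngtdm"`; `$values` is a matrix with
#'   columns `n`, `p`, `s` and one row per gray level.
#' @export
compute_ngtdm <- function(voi) {
  stopifnot(inherits(voi, "dvoi"))
  L <- voi$levels
  if (!any(L > 0)) stop("empty mask")
  d <- dim(L)
  nsum <- array(0, d)
  ncnt <- array(0L, d)
  o26 <- offsets26()
  for (i in seq_len(nrow(o26))) {
    off <- o26[i, ]
    rng <- offset_ranges(d, off)
    if (is.null(rng)) next
    a <- L[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    b <- L[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3], drop = FALSE]
    k <- a > 0L & b > 0L
    ssub <- nsum[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    csub <- ncnt[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    ssub[k] <- ssub[k] + b[k]
    csub[k] <- csub[k] + 1L
    nsum[rng[[1]], rng[[2]], rng[[3]]] <- ssub
    ncnt[rng[[1]], rng[[2]], rng[[3]]] <- csub
  }
  inm <- L > 0L
  lv <- L[inm]
  ng <- voi$n_levels
  n_i <- tabulate(lv, nbins = ng)
  diffs <- abs(lv - nsum[inm] / ncnt[inm])
  diffs[ncnt[inm] == 0L] <- 0
  s_i <- vapply(seq_len(ng), function(i) sum(diffs[lv == i]), 0)
  vals <- cbind(n = n_i, p = n_i / sum(n_i), s = s_i)
  rownames(vals) <- seq_len(ng)
  new_texture_matrix("ngtdm", vals, list(connectivity = 26L))
}
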