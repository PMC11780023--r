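# Shared fixtures and independent brute-force oracles for the texture
# matrix builders.  The oracles are plain nested loops, deliberately
# independent of the vectorized implementation they check.

mk_sphere_mask <- function(r, sp = c(1, 1, 1), pad = 3) {
  n <- ceiling(2 * (r + pad) / sp)
  ctr <- (n / 2 + 0.5) * sp
  g <- array(0, n)
  ix <- which(array(TRUE, n), arr.ind = TRUE)
  x <- sweep(sweep(ix, 2, 1 / 2, "-"), 2, sp, "*")
  g[(x[, 1] - ctr[1])^2 + (x[, 2] - ctr[2])^2 + (x[, 3] - ctr[3])^2 <= r^2] <- 1
  volume(g, sp)
}

# Random small discretized VOI: shape <= max_dim^3, levels <= max_lev,
# with a random in-mask pattern (possibly non-convex).
random_dvoi <- function(max_dim = 4, max_lev = 4, p_in = 0.7) {
  d <- sample(2:max_dim, 3, replace = TRUE)
  L <- array(0L, d)
  inm <- array(stats::runif(prod(d)) < p_in, d)
  if (!any(inm)) inm[sample(prod(d), 1)] <- TRUE
  L[inm] <- sample.int(max_lev, sum(inm), replace = TRUE)
  L[] <- as.integer(L)
  # renumber so max level is attained (dvoi invariant)
  lev <- sort(unique(L[L > 0]))
  L[L > 0] <- match(L[L > 0], lev)
  as_dvoi(L)
}

all_offsets26 <- local({
  out <- NULL
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    if (!all(c(dx, dy, dz) == 0)) out <- rbind(out, c(dx, dy, dz))
  out
})

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# --- brute-force oracles ---------------------------------------------------

glcm_brute <- function(L, off, symmetric = TRUE) {
  d <- dim(L); ng <- max(L)
  C <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- L[x, y, z]
    if (a == 0) next
    q <- c(x, y, z) + off
    if (!in_grid(q, d)) next
    b <- L[q[1], q[2], q[3]]
    if (b == 0) next
    C[a, b] <- C[a, b] + 1
    if (symmetric) C[b, a] <- C[b, a] + 1
  }
  if (sum(C) == 0) NULL else C / sum(C)
}

glrlm_brute <- function(L, off) {
  d <- dim(L); ng <- max(L)
  runs <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    v <- L[x, y, z]
    if (v == 0) next
    p_prev <- c(x, y, z) - off
    if (in_grid(p_prev, d) && L[p_prev[1], p_prev[2], p_prev[3]] == v) next
    len <- 1
    q <- c(x, y, z) + off
    while (in_grid(q, d) && L[q[1], q[2], q[3]] == v) {
      len <- len + 1
      q <- q + off
    }
    runs[[length(runs) + 1]] <- c(v, len)
  }
  if (!length(runs)) return(NULL)
  rn <- do.call(rbind, runs)
  R <- matrix(0, ng, max(rn[, 2]))
  for (i in seq_len(nrow(rn))) R[rn[i, 1], rn[i, 2]] <- R[rn[i, 1], rn[i, 2]] + 1
  R
}

glszm_brute <- function(L) {
  d <- dim(L); ng <- max(L)
  seen <- array(FALSE, d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (L[x, y, z] == 0 || seen[x, y, z]) next
    v <- L[x, y, z]
    stack <- list(c(x, y, z)); seen[x, y, z] <- TRUE; size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (k in seq_len(nrow(all_offsets26))) {
        q <- p + all_offsets26[k, ]
        if (in_grid(q, d) && !seen[q[1], q[2], q[3]] &&
            L[q[1], q[2], q[3]] == v) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(v, size)
  }
  zn <- do.call(rbind, zones)
  S <- matrix(0, ng, max(zn[, 2]))
  for (i in seq_len(nrow(zn))) S[zn[i, 1], zn[i, 2]] <- S[zn[i, 1], zn[i, 2]] + 1
  S
}

gldm_brute <- function(L, alpha = 0) {
  d <- dim(L); ng <- max(L)
  deps <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    v <- L[x, y, z]
    if (v == 0) next
    dep <- 0
    for (k in seq_len(nrow(all_offsets26))) {
      q <- c(x, y, z) + all_offsets26[k, ]
      if (in_grid(q, d) && L[q[1], q[2], q[3]] > 0 &&
          abs(L[q[1], q[2], q[3]] - v) <= alpha) dep <- dep + 1
    }
    deps[[length(deps) + 1]] <- c(v, dep)
  }
  dp <- do.call(rbind, deps)
  D <- matrix(0, ng, max(dp[, 2]) + 1)
  for (i in seq_len(nrow(dp)))
    D[dp[i, 1], dp[i, 2] + 1] <- D[dp[i, 1], dp[i, 2] + 1] + 1
  D
}

ngtdm_brute <- function(L) {
  d <- dim(L); ng <- max(L)
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    v <- L[x, y, z]
    if (v == 0) next
    n_i[v] <- n_i[v] + 1
    nb <- c()
    for (k in seq_len(nrow(all_offsets26))) {
      q <- c(x, y, z) + all_offsets26[k, ]
      if (in_grid(q, d) && L[q[1], q[2], q[3]] > 0)
        nb <- c(nb, L[q[1], q[2], q[3]])
    }
    if (length(nb)) s_i[v] <- s_i[v] + abs(v - mean(nb))
  }
  cbind(n = n_i, p = n_i / sum(n_i), s = s_i)
}

# pad matrix to given number of columns with zeros (for comparisons)
pad_cols <- function(m, nc) {
  if (ncol(m) < nc) cbind(m, matrix(0, nrow(m), nc - ncol(m))) else m
}
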