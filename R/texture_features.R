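# Per-family texture feature formulas.  Each function takes one matrix (a
# per-direction normalized GLCM, a per-direction GLRLM count matrix, etc.)
# and returns the family's named feature vector.  Degenerate single-level
# VOIs make correlation-type denominators vanish; those features return 0
# (deterministic handling of a reachable edge case).

.eps <- 2.2e-16

# 24 GLCM features from a normalized symmetric co-occurrence matrix.
glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)                       # == py by symmetry
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  # diagonal |i-j| and anti-diagonal i+j distributions (one O(ng^2) pass)
  k_diff <- 0:(ng - 1)
  p_diff <- as.vector(rowsum(as.vector(P), as.vector(abs(i - j))))
  if (length(p_diff) < ng) p_diff <- c(p_diff, rep(0, ng - length(p_diff)))
  k_sum <- 2:(2 * ng)
  p_sum <- as.vector(rowsum(as.vector(P), as.vector(i + j)))
  if (length(p_sum) < length(k_sum))
    p_sum <- c(p_sum, rep(0, length(k_sum) - length(p_sum)))
  da <- sum(k_diff * p_diff)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hxy <- -sum(P[P > 0] * log2(P[P > 0]))
  pxpy <- outer(px, px)
  hxy1 <- -sum(P[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hxy2 <- -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0]))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 0
  mcc <- glcm_mcc(P, px)
  offd <- abs(i - j) > 0
  c(Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(p_diff[p_diff > 0] * log2(p_diff[p_diff > 0])),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(P[offd] / (i - j)[offd]^2),
    JointAverage = mu,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = -sum(p_sum[p_sum > 0] * log2(p_sum[p_sum > 0])),
    SumSquares = sig2)
}

# Maximal correlation coefficient: sqrt of the second-largest eigenvalue of
# Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) px(k)).
glcm_mcc <- function(P, px) {
  keep <- px > 0
  if (sum(keep) < 2) return(0)
  Pk <- P[keep, keep, drop = FALSE]
  pxk <- px[keep]
  Q <- sweep(Pk / pxk, 2, pxk, "/") %*% t(Pk)
  ev <- tryCatch(sort(Re(eigen(Q, only.values = TRUE)$values),
                      decreasing = TRUE),
                 error = function(e) NULL)
  if (is.null(ev) || length(ev) < 2) return(0)
  sqrt(pmax(ev[2], 0))
}

# 16 run-length features from one direction's count matrix R(i, j).
glrlm_features_one <- function(R, n_voxels) {
  nr <- sum(R)
  if (nr == 0) return(stats::setNames(rep(0, 16), names(glrlm_feature_names())))
  ng <- nrow(R); nj <- ncol(R)
  i <- seq_len(ng); j <- seq_len(nj)
  gi <- rowSums(R); rj <- colSums(R)
  p <- R / nr
  mu_i <- sum(i * rowSums(p))
  mu_j <- sum(j * colSums(p))
  c(ShortRunEmphasis = sum(rj / j^2) / nr,
    LongRunEmphasis = sum(rj * j^2) / nr,
    GrayLevelNonUniformity = sum(gi^2) / nr,
    GrayLevelNonUniformityNormalized = sum(gi^2) / nr^2,
    RunLengthNonUniformity = sum(rj^2) / nr,
    RunLengthNonUniformityNormalized = sum(rj^2) / nr^2,
    RunPercentage = nr / n_voxels,
    GrayLevelVariance = sum(outer((i - mu_i)^2, rep(1, nj)) * p),
    RunVariance = sum(outer(rep(1, ng), (j - mu_j)^2) * p),
    RunEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelRunEmphasis = sum(gi / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(gi * i^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(R / outer(i^2, j^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(R * outer(i^2, 1 / j^2)) / nr,
    LongRunLowGrayLevelEmphasis = sum(R * outer(1 / i^2, j^2)) / nr,
    LongRunHighGrayLevelEmphasis = sum(R * outer(i^2, j^2)) / nr)
}

glrlm_feature_names <- function() {
  c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage",
    "GrayLevelVariance", "RunVariance", "RunEntropy",
    "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
    "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
    "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
}

# 16 size-zone features from the zone count matrix S(i, s).
glszm_features <- function(S, n_voxels) {
  nz <- sum(S)
  ng <- nrow(S); ns <- ncol(S)
  i <- seq_len(ng); s <- seq_len(ns)
  gi <- rowSums(S); zs <- colSums(S)
  p <- S / nz
  mu_i <- sum(i * rowSums(p))
  mu_s <- sum(s * colSums(p))
  c(SmallAreaEmphasis = sum(zs / s^2) / nz,
    LargeAreaEmphasis = sum(zs * s^2) / nz,
    GrayLevelNonUniformity = sum(gi^2) / nz,
    GrayLevelNonUniformityNormalized = sum(gi^2) / nz^2,
    SizeZoneNonUniformity = sum(zs^2) / nz,
    SizeZoneNonUniformityNormalized = sum(zs^2) / nz^2,
    ZonePercentage = nz / n_voxels,
    GrayLevelVariance = sum(outer((i - mu_i)^2, rep(1, ns)) * p),
    ZoneVariance = sum(outer(rep(1, ng), (s - mu_s)^2) * p),
    ZoneEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelZoneEmphasis = sum(gi / i^2) / nz,
    HighGrayLevelZoneEmphasis = sum(gi * i^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(S / outer(i^2, s^2)) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(S * outer(i^2, 1 / s^2)) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(S * outer(1 / i^2, s^2)) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(S * outer(i^2, s^2)) / nz)
}

# 14 dependence features.  D's columns index neighbour counts d = 0, 1, ...;
# formulas use j = d + 1 (the dependence size including the centre voxel) so
# small/large-dependence denominators never vanish.
gldm_features <- function(D) {
  nz <- sum(D)
  ng <- nrow(D); nd <- ncol(D)
  i <- seq_len(ng); j <- seq_len(nd)      # j = d + 1
  gi <- rowSums(D); dj <- colSums(D)
  p <- D / nz
  mu_i <- sum(i * rowSums(p))
  mu_j <- sum(j * colSums(p))
  c(SmallDependenceEmphasis = sum(dj / j^2) / nz,
    LargeDependenceEmphasis = sum(dj * j^2) / nz,
    GrayLevelNonUniformity = sum(gi^2) / nz,
    DependenceNonUniformity = sum(dj^2) / nz,
    DependenceNonUniformityNormalized = sum(dj^2) / nz^2,
    GrayLevelVariance = sum(outer((i - mu_i)^2, rep(1, nd)) * p),
    DependenceVariance = sum(outer(rep(1, ng), (j - mu_j)^2) * p),
    DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelEmphasis = sum(gi / i^2) / nz,
    HighGrayLevelEmphasis = sum(gi * i^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(D / outer(i^2, j^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(D * outer(i^2, 1 / j^2)) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(D * outer(1 / i^2, j^2)) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(D * outer(i^2, j^2)) / nz)
}

# 5 neighbouring gray tone difference features from the (n, p, s) table.
ngtdm_features <- function(tab) {
  n_i <- tab[, "n"]; p_i <- tab[, "p"]; s_i <- tab[, "s"]
  lv <- as.numeric(rownames(tab))
  pres <- p_i > 0
  i <- lv[pres]; p <- p_i[pres]; s <- s_i[pres]
  ngp <- length(i)
  nvc <- sum(n_i)
  ps <- sum(p * s)
  coarseness <- if (ps > 0) 1 / ps else 1e6
  if (ngp > 1) {
    ij2 <- outer(i, i, function(a, b) (a - b)^2)
    contrast <- (sum(outer(p, p) * ij2) / (ngp * (ngp - 1))) * (sum(s) / nvc)
    ipd <- abs(outer(i * p, i * p, "-"))
    busy <- sum(ipd)
    busyness <- if (busy > 0) ps / busy else 0
    pp <- outer(p, p, "+")
    absij <- abs(outer(i, i, "-"))
    psps <- outer(p * s, p * s, "+")
    complexity <- sum(absij * psps / pp) / nvc
    strength <- if (sum(s) > 0) sum(pp * ij2) / sum(s) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

# Direction-averaged feature vectors for GLCM / GLRLM texture objects.
glcm_features <- function(tm) {
  stopifnot(tm$kind == "glcm")
  feats <- lapply(tm$meta$matrices, glcm_features_one)
  Reduce(`+`, feats) / length(feats)
}

glrlm_features <- function(tm, n_voxels) {
  stopifnot(tm$kind == "glrlm")
  feats <- lapply(tm$meta$matrices, glrlm_features_one, n_voxels = n_voxels)
  Reduce(`+`, feats) / length(feats)
}
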