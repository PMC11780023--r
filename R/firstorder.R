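# First-order intensity statistics (18 features) over the in-mask voxels.
# Entropy and Uniformity are computed on the discretized gray levels, the
# remaining features on the continuous intensities.
firstorder_features <- function(x, levels_in_mask, voxel_volume_mm3) {
  n <- length(x)
  p <- tabulate(levels_in_mask) / n
  p <- p[p > 0]
  mu <- mean(x)
  ctr <- x - mu
  m2 <- mean(ctr^2)
  qs <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                        type = 7)
  core <- x[x >= qs[1] & x <= qs[5]]
  skew <- if (m2 > 0) mean(ctr^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(ctr^4) / m2^2 else 0
  c(Energy = sum(x^2),
    TotalEnergy = voxel_volume_mm3 * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = qs[1],
    `90Percentile` = qs[5],
    Maximum = max(x),
    Mean = mu,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(ctr)),
    RobustMeanAbsoluteDeviation = mean(abs(core - mean(core))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2))
}
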