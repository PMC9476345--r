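# The 18 first-order features: histogram statistics of in-mask
# intensities. Entropy and Uniformity use the discretized histogram
# (log base 2); moments are population moments; kurtosis is NOT
# excess-corrected (a normal sample gives ~3). Degenerate inputs
# (single voxel / constant region) return documented constants rather
# than NaN so downstream selection never silently drops subjects.

#' Names of the first-order features
#' @return Character vector of length 18.
#' @export
firstOrderNames <- function() {
  c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
    "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
    "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
    "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")
}

#' First-order features of a set of intensities
#'
#' @param values Numeric vector of in-mask intensities (>= 1 value).
#' @param levels Integer vector of the discretized levels of the same
#'   voxels (for Entropy/Uniformity).
#' @param voxelVolumeMm3 Physical volume of one voxel (for TotalEnergy).
#' @return Named numeric vector of the 18 features.
#' @export
firstOrderFeatures <- function(values, levels, voxelVolumeMm3 = 1) {
  n <- length(values)
  if (n < 1L) stop("at least one voxel required")
  p <- tabulate(levels)
  p <- p[p > 0] / n
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  qs <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90),
                        names = FALSE, type = 7)
  mid <- values[values >= qs[1] & values <= qs[5]]
  skew <- if (m2 > 0) mean((values - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((values - mu)^4) / m2^2 else 0
  c(Energy = sum(values^2),
    TotalEnergy = voxelVolumeMm3 * sum(values^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(values),
    `10Percentile` = qs[1],
    `90Percentile` = qs[5],
    Maximum = max(values),
    Mean = mu,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(mid - mean(mid))),
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2))
}
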