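#' First-order intensity features
#'
#' The 18 standard first-order statistics of the in-ROI intensity
#' distribution. Moments use population (1/n) denominators; entropy and
#' uniformity are computed on the discretized levels (base-2 logarithm);
#' total energy scales energy by the physical voxel volume.
#'
#' @param values numeric vector of in-ROI intensities (nonempty).
#' @param voxel_volume physical voxel volume in mm^3.
#' @param d discretization used for entropy/uniformity.
#' @return named numeric vector of 18 features.
#' @export
firstorder_features <- function(values, voxel_volume = 1,
                                d = discretization_spec()) {
  if (length(values) == 0) stop("empty ROI")
  n <- length(values)
  mu <- mean(values)
  v <- mean((values - mu)^2)       # population variance
  qs <- stats::quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE,
                        type = 7)
  lev <- discretize(values, d)$levels
  p <- tabulate(lev) / n
  p <- p[p > 0]
  rob <- values[values >= qs[1] & values <= qs[5]]
  sk <- if (v <= .Machine$double.eps * max(1, mu^2)) 0 else
    mean((values - mu)^3) / v^1.5
  ku <- if (v <= .Machine$double.eps * max(1, mu^2)) 0 else
    mean((values - mu)^4) / v^2
  c(
    Energy = sum(values^2),
    TotalEnergy = voxel_volume * sum(values^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(values),
    Percentile10 = qs[1],
    Percentile90 = qs[5],
    Maximum = max(values),
    Mean = mu,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = sk,
    Kurtosis = ku,
    Variance = v,
    Uniformity = sum(p^2)
  )
}
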