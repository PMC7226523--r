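#' First-order intensity statistics
#'
#' The 18 first-order features on the continuous masked intensities. Entropy
#' and Uniformity are computed on the fixed-bin-width histogram (same binning
#' convention as [discretize()]); everything else uses raw values. Skewness
#' and kurtosis are the population moment ratios and return 0 on a
#' zero-variance ROI; Kurtosis is not excess-corrected (a Gaussian gives 3).
#'
#' @param volume `image_volume` or 3-D array of intensities.
#' @param mask `image_volume` or 3-D binary array.
#' @param bin_width histogram bin width for Entropy/Uniformity.
#' @param spacing_mm voxel size, used for TotalEnergy; taken from `volume`
#'   when it is an `image_volume`.
#' @return Named numeric vector of 18 features.
#' @export
firstorder_features <- function(volume, mask, bin_width = 25, spacing_mm = NULL) {
  if (inherits(volume, "image_volume")) {
    if (is.null(spacing_mm)) spacing_mm <- volume$spacing_mm
    volume <- volume$data
  }
  if (is.null(spacing_mm)) spacing_mm <- c(1, 1, 1)
  msk <- if (inherits(mask, "image_volume")) mask$data else mask
  v <- volume[msk != 0]
  if (length(v) == 0) stop("firstorder_features: mask is empty")
  n <- length(v)
  eps <- the_eps
  mu <- mean(v)
  vv <- mean((v - mu)^2)                      # population variance
  p10 <- unname(quantile(v, 0.10, type = 7))
  p90 <- unname(quantile(v, 0.90, type = 7))
  mid <- v[v >= p10 & v <= p90]
  skew <- if (vv > 0) mean((v - mu)^3) / vv^1.5 else 0
  kurt <- if (vv > 0) mean((v - mu)^4) / vv^2 else 0
  lev <- floor((v - min(v)) / bin_width) + 1
  ph <- tabulate(lev) / n
  setNames(c(
    sum(v^2),
    prod(spacing_mm) * sum(v^2),
    -sum(ph[ph > 0] * log2(ph[ph > 0] + eps)),
    min(v), p10, p90, max(v), mu, median(v),
    unname(quantile(v, 0.75, type = 7) - quantile(v, 0.25, type = 7)),
    max(v) - min(v),
    mean(abs(v - mu)),
    if (length(mid)) mean(abs(mid - mean(mid))) else 0,
    sqrt(mean(v^2)),
    skew, kurt, vv,
    sum(ph^2)), firstorder_feature_names())
}

firstorder_feature_names <- function() c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")
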