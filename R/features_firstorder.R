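#' First-order intensity statistics of an ROI
#'
#' The standard 19-feature first-order set. Because SWI intensity is not a
#' quantitative susceptibility measure, features that read the signal scale
#' directly (minimum, maximum, mean, median, percentiles, range, RMS, total
#' energy) are tagged signal-based; [texture_safe_features()] drops them
#' before feature selection.
#'
#' @param vol a [volume()].
#' @param mask a [label_mask()] or logical array on the same grid.
#' @param structure structure name (ignored for logical masks).
#' @param width bin width used for the histogram-based entropy/uniformity.
#' @return named numeric vector of 19 features (prefix `firstorder_`) with
#'   attribute `signal_based` listing the tagged names.
#' @export
first_order_features <- function(vol, mask, structure = "putamen",
                                 width = 25) {
  sel <- if (is.logical(mask)) mask else structure_mask(mask, structure)
  if (!any(sel)) stop("empty ROI")
  x <- vol$data[sel]
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                       type = 7)
  mid <- x[x >= q[1] & x <= q[5]]
  lev <- floor((x - min(x)) / width) + 1
  p <- tabulate(lev) / n
  p <- p[p > 0]
  vv <- prod(vol$spacing)
  out <- c(Energy = sum(x^2),
           TotalEnergy = vv * sum(x^2),
           Entropy = -sum(p * log2(p)),
           Minimum = min(x),
           `10Percentile` = q[1],
           `90Percentile` = q[5],
           Maximum = max(x),
           Mean = mu,
           Median = q[3],
           InterquartileRange = q[4] - q[2],
           Range = max(x) - min(x),
           MeanAbsoluteDeviation = mean(abs(x - mu)),
           RobustMeanAbsoluteDeviation = mean(abs(mid - mean(mid))),
           RootMeanSquared = sqrt(mean(x^2)),
           StandardDeviation = sqrt(m2),
           Skewness = if (m2 == 0) 0 else m3 / m2^1.5,
           Kurtosis = if (m2 == 0) 0 else m4 / m2^2,
           Variance = m2,
           Uniformity = sum(p^2))
  names(out) <- paste0("firstorder_", names(out))
  attr(out, "signal_based") <- paste0("firstorder_", signal_based_names())
  out
}

#' Default signal-based first-order feature names (unprefixed)
#'
#' The seven scale-reading statistics plus RootMeanSquared and TotalEnergy.
#' The membership is configuration-visible because the boundary between
#' signal- and texture-reading first-order statistics is a modeling choice.
#' @export
signal_based_names <- function() {
  c("Minimum", "Maximum", "Mean", "Median", "10Percentile", "90Percentile",
    "Range", "RootMeanSquared", "TotalEnergy")
}

#' Drop signal-based features from a feature vector
#'
#' @param fv named feature vector (e.g. from [extract_all()]).
#' @param exclude unprefixed first-order names to drop
#'   (default [signal_based_names()]).
#' @return the filtered vector.
#' @export
texture_safe_features <- function(fv, exclude = signal_based_names()) {
  fv[!names(fv) %in% paste0("firstorder_", exclude)]
}
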