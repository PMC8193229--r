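## First-order (intensity) features: 16 whole-frame statistics.

INTENSITY_NAMES <- c("mean", "median", "minimum", "maximum", "range",
                     "variance", "std_dev", "skewness", "kurtosis",
                     "energy", "rms", "entropy", "uniformity",
                     "mean_abs_dev", "p10", "p90")

#' 16 first-order intensity features of a frame
#'
#' Whole-frame statistics (no ROI mask): mean, median, minimum, maximum,
#' range, variance, standard deviation, skewness, kurtosis, energy (sum of
#' squares), root mean square, histogram entropy (256 equal-width bins over
#' the frame's range, log base 2, with 0 log 0 = 0), uniformity (sum of
#' squared bin probabilities), mean absolute deviation, and the 10th and
#' 90th percentiles (type-7 quantiles). Variance and the moment features
#' use the population (n) denominator; skewness and kurtosis of a constant
#' frame are defined as 0 (kurtosis is the non-excess form otherwise).
#'
#' @param frame Numeric matrix.
#' @return Named numeric vector of length 16.
#' @export
intensity_features <- function(frame) {
  x <- as.numeric(frame)
  if (length(x) == 0L) stop_("frame is empty")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  sdv <- sqrt(m2)
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  rng <- range(x)
  ## 256-bin histogram entropy/uniformity over [min, max]
  if (rng[2] > rng[1]) {
    bins <- pmin(256L, floor((x - rng[1]) / (rng[2] - rng[1]) * 256) + 1L)
    p <- tabulate(bins, 256L) / n
  } else {
    p <- c(1, rep(0, 255L))
  }
  p_nz <- p[p > 0]
  stats::setNames(c(
    mu, stats::median(x), rng[1], rng[2], rng[2] - rng[1],
    m2, sdv, skew, kurt,
    sum(x^2), sqrt(mean(x^2)),
    -sum(p_nz * log2(p_nz)), sum(p^2),
    mean(abs(x - mu)),
    stats::quantile(x, 0.10, names = FALSE),
    stats::quantile(x, 0.90, names = FALSE)
  ), INTENSITY_NAMES)
}
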