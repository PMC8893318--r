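#' First-order intensity statistics of the region of interest
#'
#' The 18 standard first-order radiomics features. Percentiles use linear
#' interpolation (R quantile type 7). Entropy (base 2) and uniformity are
#' computed on the fixed-bin-count discretized ROI. Degenerate rules for a
#' constant ROI: entropy 0, uniformity 1, skewness 0, kurtosis 0.
#' Kurtosis is the non-excess (Pearson) form; variance, standard deviations
#' and moments are population quantities.
#'
#' @param volume Preprocessed [volume_image()].
#' @param mask Aligned [seg_mask()].
#' @param n_bins Gray levels for the entropy/uniformity histogram.
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(volume, mask, n_bins = 32) {
  stopifnot(inherits(volume, "volume_image"), inherits(mask, "seg_mask"))
  .check_aligned(volume, mask)
  sel <- mask$data == 1L
  if (!any(sel)) .anf_stop("anf_roi_error", "empty region of interest")
  x <- volume$data[sel]
  n <- length(x)
  voxvol <- prod(volume$spacing)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                       type = 7)
  in1090 <- x[x >= q[1] & x <= q[5]]
  rmad <- if (length(in1090)) mean(abs(in1090 - mean(in1090))) else 0
  roi <- discretize(volume, mask, n_bins = max(2, n_bins))
  p <- tabulate(roi$levels[sel], nbins = roi$n_levels) / n
  p <- p[p > 0]
  c(energy = sum(x^2),
    total_energy = voxvol * sum(x^2),
    entropy = -sum(p * log2(p)),
    minimum = min(x),
    percentile10 = q[1],
    percentile90 = q[5],
    maximum = max(x),
    mean = mu,
    median = q[3],
    interquartile_range = q[4] - q[2],
    range = max(x) - min(x),
    mean_absolute_deviation = mean(abs(x - mu)),
    robust_mad = rmad,
    root_mean_squared = sqrt(mean(x^2)),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    variance = m2,
    uniformity = sum(p^2))
}
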