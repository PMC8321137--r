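#' Equal-width gray-level discretization
#'
#' Bins masked intensities into `ng` equal-width levels over the masked
#' [min, max] range; the minimum maps to level 1 and the maximum to level
#' `ng`. A constant region maps entirely to level 1.
#'
#' @param vol an [MRVolume-class].
#' @param mask binary [MRVolume-class] on the same grid.
#' @param ng number of gray levels (>= 2).
#' @return A `discretized_volume`: list with `levels` (3D integer array, 0
#'   outside the mask), `mask` (logical array), `ng`, `breaks`,
#'   `voxelVolume`.
#' @export
discretizeVolume <- function(vol, mask, ng = 32L) {
  if (ng < 2L) stop("ng must be >= 2")
  m <- mask@voxels > 0
  if (!any(m)) stop("mask is empty")
  v <- vol@voxels[m]
  lo <- min(v); hi <- max(v)
  lev <- array(0L, gridDim(vol))
  if (hi - lo < 1e-12) {
    lev[m] <- 1L
    breaks <- c(lo, hi)
  } else {
    breaks <- seq(lo, hi, length.out = ng + 1L)
    lev[m] <- pmin(pmax(findInterval(v, breaks, all.inside = TRUE), 1L),
                   as.integer(ng))
  }
  structure(list(levels = lev, mask = m, ng = as.integer(ng),
                 breaks = breaks, voxelVolume = prod(vol@spacing),
                 spacing = vol@spacing),
            class = "discretized_volume")
}

#' First-order intensity statistics
#'
#' The 16 histogram/intensity features over masked voxels: energy (sum of
#' squares), total energy (energy x voxel volume), histogram entropy
#' (base 2, `ng` equal-width bins), minimum, 10th / 90th percentiles,
#' maximum, mean, median, range, mean absolute deviation (from the mean),
#' root mean square, skewness and kurtosis (population moments, kurtosis
#' non-excess), standard deviation (population), and uniformity (sum of
#' squared histogram probabilities).
#'
#' @param vol an [MRVolume-class].
#' @param mask binary [MRVolume-class] on the same grid.
#' @param ng histogram bins for entropy/uniformity.
#' @return Named numeric(16).
#' @export
firstOrderFeatures <- function(vol, mask, ng = 32L) {
  m <- mask@voxels > 0
  if (!any(m)) stop("mask is empty")
  v <- vol@voxels[m]
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  sdev <- sqrt(m2)
  skew <- if (m2 < 1e-24) 0 else mean((v - mu)^3) / m2^1.5
  kurt <- if (m2 < 1e-24) 0 else mean((v - mu)^4) / m2^2
  # histogram probabilities on ng equal-width bins over the masked range
  if (max(v) - min(v) < 1e-12) {
    p <- 1
  } else {
    br <- seq(min(v), max(v), length.out = ng + 1L)
    cnt <- tabulate(pmin(pmax(findInterval(v, br, all.inside = TRUE), 1L),
                         as.integer(ng)), nbins = as.integer(ng))
    p <- cnt[cnt > 0] / n
  }
  q <- quantile(v, c(0.10, 0.90), names = FALSE, type = 7)
  c(energy = sum(v^2),
    total.energy = sum(v^2) * prod(vol@spacing),
    entropy = -sum(p * log2(p)),
    minimum = min(v),
    p10 = q[1], p90 = q[2],
    maximum = max(v),
    mean = mu,
    median = median(v),
    range = max(v) - min(v),
    mad = mean(abs(v - mu)),
    rms = sqrt(mean(v^2)),
    skewness = skew,
    kurtosis = kurt,
    sd = sdev,
    uniformity = sum(p^2))
}
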