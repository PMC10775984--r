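#' Instantaneous firing rate series
#'
#' Assigns each spike to its nearest position sample in time, then convolves
#' the per-sample spike counts with a unit-gain Blackman window of
#' `window * sample_rate` samples (rounded to an odd count) and divides by
#' the sampling interval.  Because the window has unit gain, the series
#' times the sampling interval sums to the number of spikes (up to edge
#' truncation of spikes very near the session boundaries).
#'
#' @param traj A `trajectory`.
#' @param spikes A `spike_train`.
#' @param window Window duration in seconds (at least one sampling
#'   interval).
#' @return Numeric vector of rates (Hz), one per position sample.
#' @examples
#' # a 0.125 s window at 50 Hz spans 7 samples
#' @export
instantaneous_rate <- function(traj, spikes, window = 0.125) {
  sr <- traj$arena$sample_rate
  if (window < 1 / sr) stop("window must be at least one sampling interval")
  n <- length(traj$t)
  idx <- pmin(pmax(round(spikes$spike_t * sr) + 1L, 1L), n)
  counts <- tabulate(idx, nbins = n)
  nw <- blackman_length(window, sr)
  if (nw <= 1) return(counts * sr)
  w <- signal::blackman(nw)
  w <- w / sum(w)
  half <- (nw - 1) / 2
  padded <- c(numeric(half), counts, numeric(half))
  sm <- stats::filter(padded, w, method = "convolution", sides = 2)
  as.numeric(sm[(half + 1):(half + n)]) * sr
}

# nearest odd sample count for a window of `window` seconds
blackman_length <- function(window, sample_rate) {
  2L * as.integer(floor(window * sample_rate / 2)) + 1L
}

#' Temporal KSDE firing rate map
#'
#' Spatial mapping of the instantaneous firing rate: the value at each query
#' point is the Gaussian-distance-weighted average (weights normalized to
#' sum one) of the [instantaneous_rate()] series over all position samples.
#' Unlike the ratio estimators, each pass through a location contributes its
#' own local rate, so the method is sensitive to the temporal consistency of
#' spatial firing.  Query points farther than `empty_cutoff` from any
#' position sample are missing.
#'
#' @param traj A `trajectory`.
#' @param spikes A `spike_train`.
#' @param bin_size Query grid spacing in mm.
#' @param sigma Spatial Gaussian weighting standard deviation in mm.
#' @param window Temporal Blackman window duration in seconds.
#' @param empty_cutoff Distance cutoff (mm) for the empty-bin rule.
#' @return A `rate_map`.
#' @export
tksde_map <- function(traj, spikes, bin_size, sigma, window = 0.125,
                      empty_cutoff = 50) {
  stopifnot(sigma > 0)
  grid <- map_grid(traj$arena, bin_size)
  f <- instantaneous_rate(traj, spikes, window)
  qx <- grid_centers_x(grid)
  qy <- grid_centers_y(grid)
  Gx <- exp(-outer(traj$x, qx, "-")^2 / (2 * sigma^2))
  Gy <- exp(-outer(traj$y, qy, "-")^2 / (2 * sigma^2))
  num <- crossprod(Gx * f, Gy)
  den <- crossprod(Gx, Gy)
  rate <- num / den
  rate[den <= 0] <- NA_real_
  rate[ksde_empty_mask(traj, qx, qy, empty_cutoff)] <- NA_real_
  new_rate_map(rate, grid, "tksde",
               list(bin_size = bin_size, sigma = sigma, window = window,
                    empty_cutoff = empty_cutoff))
}
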