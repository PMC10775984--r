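#' Radii searched by the adaptive estimators
#'
#' 32 linearly spaced radii from one bin width to 640 mm (or to the bin
#' width itself if it already exceeds 640 mm).
#'
#' @param bin_size Bin side length in mm.
#' @param n_radii Number of radii.
#' @param max_radius Largest radius in mm.
#' @return Numeric vector of radii (mm).
#' @export
adaptive_radii <- function(bin_size, n_radii = 32, max_radius = 640) {
  seq(bin_size, max(bin_size, max_radius), length.out = n_radii)
}

# Shared driver for both adaptive estimators.
# mode "bin": expand until enclosed dwell >= t seconds.
# mode "smooth": expand until r >= alpha / (n_p sqrt(n_s)), r in bin widths.
adaptive_map_impl <- function(traj, spikes, bin_size, param, mode,
                              impl = c("convolution", "pixelwise"),
                              n_radii = 32, max_radius = 640) {
  impl <- match.arg(impl)
  grid <- map_grid(traj$arena, bin_size)
  radii <- adaptive_radii(bin_size, n_radii, max_radius)
  fs <- 1 / traj$arena$sample_rate
  thr <- if (mode == "bin") param / fs else param

  if (impl == "convolution") {
    b <- bin_data(traj, spikes, grid)
    res <- adaptive_expand_cpp(b$pos_counts, b$spike_counts, radii / bin_size,
                               thr, fs, if (mode == "bin") 1L else 2L)
    rate <- matrix(res$rates[, 1], grid$nx, grid$ny)
    ridx <- matrix(res$ridx[, 1], grid$nx, grid$ny)
  } else {
    qx <- grid_centers_x(grid)
    qy <- grid_centers_y(grid)
    rate <- matrix(NA_real_, grid$nx, grid$ny)
    ridx <- matrix(0L, grid$nx, grid$ny)
    r2 <- radii^2
    for (j in seq_len(grid$ny)) {
      dy2p <- (traj$y - qy[j])^2
      dy2s <- (spikes$spike_y - qy[j])^2
      for (i in seq_len(grid$nx)) {
        dp <- sort((traj$x - qx[i])^2 + dy2p)
        ds <- sort((spikes$spike_x - qx[i])^2 + dy2s)
        np <- findInterval(r2, dp)
        ns <- findInterval(r2, ds)
        sat <- if (mode == "bin") np >= thr else
          np * sqrt(ns) * (radii / bin_size) >= thr & ns > 0
        k <- which(sat)[1]
        if (!is.na(k)) {
          rate[i, j] <- ns[k] / (np[k] * fs)
          ridx[i, j] <- k
        }
      }
    }
  }
  list(rate = rate, ridx = ridx, grid = grid, radii = radii)
}

#' Adaptive smoothing (Skaggs-McNaughton) firing rate map
#'
#' For every bin a circular neighbourhood is expanded through 32 candidate
#' radii (one bin width to 640 mm) until the enclosed position-sample count
#' `n_p` and spike count `n_s` satisfy the criterion
#' `r >= alpha / (n_p * sqrt(n_s))`, with `r` measured in bin widths.  The
#' bin's rate is then `n_s / (n_p * f_s)` in Hz.  Bins for which no searched
#' radius satisfies the criterion (in particular bins with no spikes within
#' the largest radius) are missing.
#'
#' The `"convolution"` implementation counts samples via circular unity-gain
#' kernels applied to pre-binned, zero-padded maps; `"pixelwise"` measures
#' true point-to-point distances from each bin centre.  The two give
#' near-identical maps, the convolution form in a fraction of the time.
#'
#' @param traj A `trajectory`.
#' @param spikes A `spike_train`.
#' @param bin_size Bin side length in mm.
#' @param alpha Smoothing parameter (dimensionless, typically 100-32000).
#' @param impl `"convolution"` or `"pixelwise"`.
#' @return A `rate_map`; `$params$radius_idx` holds the chosen radius index
#'   per bin (0 = unsatisfied).
#' @export
adaptive_smooth_map <- function(traj, spikes, bin_size, alpha,
                                impl = c("convolution", "pixelwise")) {
  r <- adaptive_map_impl(traj, spikes, bin_size, alpha, "smooth", impl)
  new_rate_map(r$rate, r$grid, "adaptive_smooth",
               list(bin_size = bin_size, alpha = alpha,
                    radii = r$radii, radius_idx = r$ridx))
}

#' Adaptive binning (dwell-time) firing rate map
#'
#' K-nearest-neighbour-style estimator: for every bin a circular
#' neighbourhood is expanded through 32 candidate radii until it encloses at
#' least `t` seconds of dwell time; the rate is then enclosed spikes divided
#' by enclosed dwell seconds.  Bins never reaching `t` seconds within the
#' largest radius are missing; if the whole session is shorter than `t` the
#' map is all-missing and a warning is raised.
#'
#' @param traj A `trajectory`.
#' @param spikes A `spike_train`.
#' @param bin_size Bin side length in mm.
#' @param t Minimum enclosed dwell time in seconds.
#' @param impl `"convolution"` or `"pixelwise"`.
#' @return A `rate_map`.
#' @export
adaptive_bin_map <- function(traj, spikes, bin_size, t,
                             impl = c("convolution", "pixelwise")) {
  if (t > length(traj$t) / traj$arena$sample_rate)
    warning("session is shorter than the dwell criterion t; map is empty")
  r <- adaptive_map_impl(traj, spikes, bin_size, t, "bin", impl)
  new_rate_map(r$rate, r$grid, "adaptive_bin",
               list(bin_size = bin_size, t = t,
                    radii = r$radii, radius_idx = r$ridx))
}
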