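#' Bivariate histogram firing rate map
#'
#' The classic estimator: spike and dwell maps are binned on a common grid
#' and the rate is their ratio in Hz.  With
#' `smooth_stage = "before_division"` (the default, and the more accurate
#' choice on typical data) the spike and dwell maps are Gaussian smoothed
#' before dividing, and bins whose smoothed dwell is zero are missing.  With
#' `"after_division"` the raw ratio is computed first and then smoothed with
#' the missing-value-aware kernel, which confines estimates to visited bins.
#' `"none"` returns the raw ratio.
#'
#' @param traj A `trajectory`.
#' @param spikes A `spike_train`.
#' @param bin_size Bin side length in mm.
#' @param sigma Gaussian smoothing standard deviation in mm (0 = none).
#' @param smooth_stage `"before_division"`, `"after_division"` or `"none"`.
#' @return A `rate_map`.
#' @examples
#' a <- arena_spec()
#' tr <- simulate_random_walk(a, duration = 30, seed = 1)
#' cell <- simulate_place_cell(a, "medium", seed = 2)
#' sp <- simulate_spikes(cell, tr, seed = 3)
#' histogram_map(tr, sp, bin_size = 50, sigma = 50)
#' @export
histogram_map <- function(traj, spikes, bin_size, sigma = 0,
                          smooth_stage = c("before_division",
                                           "after_division", "none")) {
  smooth_stage <- match.arg(smooth_stage)
  grid <- map_grid(traj$arena, bin_size)
  b <- bin_data(traj, spikes, grid)
  if (sum(b$dwell) <= 0) stop("trajectory has zero total dwell time")
  if (smooth_stage == "before_division" && sigma > 0) {
    sm_s <- gaussian_smooth(b$spike_counts, sigma, bin_size)
    sm_d <- gaussian_smooth(b$dwell, sigma, bin_size)
    rate <- sm_s / sm_d
    rate[sm_d == 0] <- NA_real_
  } else {
    rate <- b$spike_counts / b$dwell
    rate[b$dwell == 0] <- NA_real_
    if (smooth_stage == "after_division" && sigma > 0)
      rate <- nan_aware_smooth(rate, sigma, bin_size)
  }
  new_rate_map(rate, grid, "histogram",
               list(bin_size = bin_size, sigma = sigma,
                    smooth_stage = smooth_stage))
}
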