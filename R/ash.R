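#' Quartic (biweight) kernel
#'
#' `k(t) = 15/16 (1 - t^2)^2` for `|t| <= 1`, zero otherwise; the weighting
#' kernel of the averaged shifted histogram.
#'
#' @param t Numeric vector.
#' @return Kernel values.
#' @examples
#' quartic_kernel(0)  # 15/16
#' @export
quartic_kernel <- function(t) ifelse(abs(t) <= 1, 15 / 16 * (1 - t^2)^2, 0)

ash_weights <- function(m) {
  i <- seq(1 - m, m - 1)
  k <- quartic_kernel(i / m)
  m * k / sum(k)
}

#' Averaged shifted histogram (ASH) firing rate map
#'
#' Averages `m^2` histograms with mutually offset bin origins, which is
#' equivalent to binning on a sub-grid of side `h / m` and convolving with a
#' separable quartic (biweight) kernel of half-width `h`.  Spike and dwell
#' ASHs are formed on the sub-grid (zero padded) and divided, giving a rate
#' map whose resolution is `m` times finer per axis than the nominal bin
#' size; `m = 1` reduces to the unsmoothed bivariate histogram.
#'
#' @param traj A `trajectory`.
#' @param spikes A `spike_train`.
#' @param bin_size Nominal bin side length `h` in mm.
#' @param m Integer number of shifted histograms per axis.
#' @return A `rate_map` on the `h / m` sub-grid; sub-bins with zero dwell
#'   ASH are missing.
#' @export
ash_map <- function(traj, spikes, bin_size, m = 8) {
  if (length(m) != 1 || !is.finite(m) || m != round(m) || m < 1)
    stop("m must be a positive integer")
  m <- as.integer(m)
  coarse <- map_grid(traj$arena, bin_size)
  delta <- bin_size / m
  fine <- coarse
  fine$h <- delta
  fine$nx <- coarse$nx * m
  fine$ny <- coarse$ny * m
  class(fine) <- "map_grid"
  b <- bin_data(traj, spikes, fine)
  w <- ash_weights(m)
  ash_p <- conv_sep_cpp(b$pos_counts, w, w)
  ash_s <- conv_sep_cpp(b$spike_counts, w, w)
  rate <- ash_s / (ash_p * b$fs)
  rate[ash_p == 0] <- NA_real_
  new_rate_map(rate, fine, "ash", list(bin_size = bin_size, m = m))
}
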