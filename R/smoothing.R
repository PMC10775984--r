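gaussian_kernel_1d <- function(sigma_bins) {
  half <- ceiling(2 * sigma_bins)
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma_bins^2))
  k / sum(k)
}

#' Gaussian smoothing of a binned map
#'
#' Convolves a matrix with a unit-sum Gaussian kernel whose side length is
#' `2 * ceiling(2 * sigma / h) + 1` bins (always odd, at least four standard
#' deviations wide).  The map is implicitly zero padded, so mass near the
#' edges is attenuated rather than extrapolated.  `sigma = 0` is a no-op.
#'
#' @param m A numeric matrix (e.g. spike or dwell map).
#' @param sigma Kernel standard deviation in mm.
#' @param h Bin side length in mm.
#' @param padding Boundary handling; only `"zero"` is currently implemented.
#' @return A matrix of the same dimensions.
#' @examples
#' m <- matrix(0, 7, 7); m[4, 4] <- 1
#' sum(gaussian_smooth(m, sigma = 50, h = 50))
#' @export
gaussian_smooth <- function(m, sigma, h, padding = "zero") {
  stopifnot(is.matrix(m), sigma >= 0, h > 0)
  padding <- match.arg(padding, "zero")
  if (sigma == 0) return(m)
  k <- gaussian_kernel_1d(sigma / h)
  conv_sep_cpp(m, k, k)
}

#' Missing-value-aware Gaussian smoothing of a rate map
#'
#' Smooths a map that contains missing (NA) bins without propagating them:
#' for each output bin the kernel weights are renormalized over the
#' non-missing neighbours (weights always sum to one), and bins missing on
#' input remain missing on output.  Intended for rate maps produced by
#' dividing unsmoothed spike and dwell maps ("smoothing after division").
#'
#' @param m A numeric matrix, possibly containing NA.
#' @param sigma Kernel standard deviation in mm.
#' @param h Bin side length in mm.
#' @return A matrix of the same dimensions with the same NA support.
#' @export
nan_aware_smooth <- function(m, sigma, h) {
  stopifnot(is.matrix(m), sigma >= 0, h > 0)
  if (sigma == 0) return(m)
  miss <- is.na(m)
  if (all(miss)) return(m)
  k <- gaussian_kernel_1d(sigma / h)
  filled <- m
  filled[miss] <- 0
  num <- conv_sep_cpp(filled, k, k)
  # kernel weight falling on missing bins; the zero padding itself counts
  # as valid, so a fully observed map reproduces gaussian_smooth() exactly
  wmiss <- conv_sep_cpp(matrix(as.numeric(miss), nrow(m), ncol(m)), k, k)
  den <- 1 - wmiss
  out <- num / den
  out[den <= 0] <- NA_real_
  out[miss] <- NA_real_
  out
}
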