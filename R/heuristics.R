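#' Ripley's K, L and H functions of a planar point pattern
#'
#' `K(r)` is the mean, over points, of the number of other points within
#' distance `r`, divided by the overall point density `lambda = n / area`
#' (no edge correction is applied, which biases `K` downward near the
#' boundary).  `L(r) = sqrt(K(r) / pi)` equals `r` in expectation for
#' complete spatial randomness, and `H(r) = L(r) - r` peaks near the radius
#' of dense clusters.
#'
#' @param x,y Point coordinates in mm (at least two points).
#' @param radii Radii (mm) at which to evaluate; sorted ascending.
#' @param area Study-region area in mm^2 (the arena rectangle).
#' @return A data frame with columns `r`, `K`, `L`, `H`; attributes
#'   `n_points` and `lambda`.
#' @export
ripley_h <- function(x, y, radii, area) {
  stopifnot(length(x) == length(y), area > 0, all(radii > 0))
  n <- length(x)
  if (n < 2) stop("at least two points are required")
  radii <- sort(radii)
  lambda <- n / area
  counts <- pair_counts_cpp(as.numeric(x), as.numeric(y), radii)
  K <- counts / n / lambda
  L <- sqrt(K / pi)
  out <- data.frame(r = radii, K = K, L = L, H = L - radii)
  attr(out, "n_points") <- n
  attr(out, "lambda") <- lambda
  out
}

#' Estimate average firing field radius from spike positions
#'
#' Field size is estimated without a rate map as 0.75 times the radius at
#' which Ripley's `H(r)` of the spike point pattern is maximal.  The peak of
#' `H` tracks the clustering radius of the pattern; the 0.75 multiplier
#' calibrates it to the 2 SD field radius of place-field-like clusters
#' whose spacing is not constrained.
#'
#' @param spikes A `spike_train` (or a list with `spike_x`, `spike_y`).
#' @param arena An [arena_spec()] providing the study region.
#' @param radii Radii searched; default 64 linearly spaced radii from 5 mm
#'   to half the arena width.
#' @return Estimated field radius in mm.
#' @export
estimate_field_radius <- function(spikes, arena,
                                  radii = seq(5, arena$width / 2,
                                              length.out = 64)) {
  x <- spikes$spike_x
  y <- spikes$spike_y
  if (length(x) < 2) stop("too few spikes to estimate a field radius")
  if (sd(x) == 0 && sd(y) == 0) stop("degenerate (coincident) spike set")
  rc <- ripley_h(x, y, radii, area = arena$width * arena$height)
  0.75 * rc$r[which.max(rc$H)]
}

#' Sturges' rule bin size
#'
#' `nbins = ceiling(log2(N) + 1)` applied to both axes; the bin size is the
#' arena width divided by `nbins`, truncated to whole millimetres.
#'
#' @param n_samples Number of position samples.
#' @param arena An [arena_spec()].
#' @return Bin size in mm.
#' @examples
#' sturges_bins(16 * 60 * 50, arena_spec())  # 70 mm
#' @export
sturges_bins <- function(n_samples, arena) {
  if (!is.finite(n_samples) || n_samples < 1) stop("need at least one sample")
  nbins <- ceiling(log2(n_samples) + 1)
  floor(arena$width / nbins)
}

#' Freedman-Diaconis rule bin size for position data
#'
#' The one-dimensional rule gives a bin width of `2 * IQR(x) * N^(-1/3)`.
#' Two bivariate extensions are provided: `"per_axis"` applies the rule to
#' the x and y coordinates separately and returns the larger of the two
#' widths; `"l2_norm"` applies it to the pooled vector norms
#' `sqrt(x^2 + y^2)` and uses the resulting width on both axes.
#'
#' @param x,y Position coordinates in mm.
#' @param variant `"per_axis"` or `"l2_norm"`.
#' @return Bin size in mm.
#' @export
fd_bins <- function(x, y, variant = c("per_axis", "l2_norm")) {
  variant <- match.arg(variant)
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  width1 <- function(v) {
    iqr <- IQR(v)
    if (iqr <= 0) stop("zero interquartile range")
    2 * iqr * n^(-1 / 3)
  }
  if (variant == "per_axis") max(width1(x), width1(y))
  else width1(sqrt(x^2 + y^2))
}
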