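# Per-axis Gaussian kernel matrix between data values d (length n) and query
# values q (length m), optionally adding reflected copies of the data across
# the axis limits [0, lim] (boundary correction for densities estimated near
# walls).
axis_kernel <- function(d, q, h, lim, reflect) {
  G <- exp(-outer(d, q, "-")^2 / (2 * h^2))
  if (reflect) {
    G <- G + exp(-outer(-d, q, "-")^2 / (2 * h^2)) +
      exp(-outer(2 * lim - d, q, "-")^2 / (2 * h^2))
  }
  G
}

# Query points farther than `cutoff` mm from any position sample are flagged
# empty.  Distances are evaluated between 1 mm-binned positions and the
# query points rounded onto the same lattice, so the rule is exact to within
# about a millimetre and independent of the query-grid density.
ksde_empty_mask <- function(traj, qx, qy, cutoff) {
  arena <- traj$arena
  g1 <- structure(list(x0 = 0, y0 = 0, h = 1,
                       nx = round(arena$width), ny = round(arena$height),
                       arena = arena), class = "map_grid")
  counts <- bin_counts(traj$x, traj$y, g1)
  qmat <- expand.grid(i = seq_along(qx), j = seq_along(qy))
  qi <- pmin(pmax(ceiling(qx[qmat$i]), 1L), g1$nx)
  qj <- pmin(pmax(ceiling(qy[qmat$j]), 1L), g1$ny)
  ok <- disc_any_cpp(counts, qi, qj, cutoff)
  matrix(!ok, length(qx), length(qy))
}

#' Kernel smoothed density estimate (KSDE) firing rate map
#'
#' Estimates the rate at each query point as the ratio of a Gaussian kernel
#' density sum over spike locations and a kernel density sum over position
#' samples (times the sampling interval):
#' `rate(x) = sum_i K((s_i - x)/h) / (f_s * sum_t K((y_t - x)/h))`.
#' The estimate is continuous, so the query grid spacing (`bin_size`) sets
#' resolution only: values at a given location do not depend on how densely
#' the map is queried.  Data are reflected across all four arena walls
#' before summation (reflection boundary correction), and query points
#' farther than `empty_cutoff` from any position sample are set missing.
#'
#' @param traj A `trajectory`.
#' @param spikes A `spike_train`.
#' @param bin_size Query grid spacing in mm.
#' @param bandwidth Gaussian kernel standard deviation `h` in mm (isotropic).
#' @param empty_cutoff Distance cutoff (mm) for the empty-bin rule.
#' @param reflect Apply reflection boundary correction.
#' @param impl `"grid"` evaluates all query points with BLAS matrix
#'   products; `"pixelwise"` loops over query points summing kernels
#'   directly (reference implementation).
#' @return A `rate_map`.
#' @export
ksde_map <- function(traj, spikes, bin_size, bandwidth, empty_cutoff = 50,
                     reflect = TRUE, impl = c("grid", "pixelwise")) {
  impl <- match.arg(impl)
  stopifnot(bandwidth > 0)
  grid <- map_grid(traj$arena, bin_size)
  fs <- 1 / traj$arena$sample_rate
  qx <- grid_centers_x(grid)
  qy <- grid_centers_y(grid)
  W <- traj$arena$width
  H <- traj$arena$height
  if (impl == "grid") {
    Gx_p <- axis_kernel(traj$x, qx, bandwidth, W, reflect)
    Gy_p <- axis_kernel(traj$y, qy, bandwidth, H, reflect)
    den <- crossprod(Gx_p, Gy_p) * fs
    Gx_s <- axis_kernel(spikes$spike_x, qx, bandwidth, W, reflect)
    Gy_s <- axis_kernel(spikes$spike_y, qy, bandwidth, H, reflect)
    num <- crossprod(Gx_s, Gy_s)
  } else {
    # reference implementation: per query point, per-axis kernel values of
    # every data point (plus its reflections) multiplied and summed
    g <- function(u) exp(-u^2 / (2 * bandwidth^2))
    kern1 <- function(d, q, lim)
      if (reflect) g(d - q) + g(-d - q) + g(2 * lim - d - q) else g(d - q)
    num <- den <- matrix(0, grid$nx, grid$ny)
    for (j in seq_len(grid$ny)) {
      kyp <- kern1(traj$y, qy[j], H)
      kys <- kern1(spikes$spike_y, qy[j], H)
      for (i in seq_len(grid$nx)) {
        den[i, j] <- sum(kern1(traj$x, qx[i], W) * kyp) * fs
        num[i, j] <- sum(kern1(spikes$spike_x, qx[i], W) * kys)
      }
    }
  }
  rate <- num / den
  rate[den <= 0] <- NA_real_
  rate[ksde_empty_mask(traj, qx, qy, empty_cutoff)] <- NA_real_
  new_rate_map(rate, grid, "ksde",
               list(bin_size = bin_size, bandwidth = bandwidth,
                    empty_cutoff = empty_cutoff, reflect = reflect))
}
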