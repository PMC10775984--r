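# Expand a rate map to the 1 mm lattice of its arena by nearest-neighbour
# (parent-bin) interpolation.  Rows index x.
upsample_1mm <- function(ratemap) {
  g <- ratemap$grid
  W <- round(g$arena$width)
  H <- round(g$arena$height)
  cx <- seq_len(W) - 0.5
  cy <- seq_len(H) - 0.5
  pi_ <- pmin(pmax(bin_index(cx, g$x0, g$h, g$nx), 1L), g$nx)
  pj <- pmin(pmax(bin_index(cy, g$y0, g$h, g$ny), 1L), g$ny)
  ratemap$rate[pi_, pj, drop = FALSE]
}

truth_surface <- function(truth) {
  if (inherits(truth, "place_cell")) truth$prob_map
  else if (is.matrix(truth)) truth
  else stop("truth must be a place_cell or a probability matrix")
}

#' Mean integrated squared error of a rate map
#'
#' Compares a firing rate map with the ground-truth spike probability
#' surface.  The rate map is interpolated to 1 mm precision by
#' nearest-neighbour interpolation; both surfaces are then normalized to
#' unit sum over the jointly non-missing 1 mm support (cells whose parent
#' map bin is missing are excluded), and the error is the mean over that
#' support of the squared difference, i.e. a Riemann sum with
#' `dx = dy = 1` mm.  Units are integrated probability squared, not firing
#' rate, and the measure is invariant to rescaling the rate map.
#'
#' @param ratemap A `rate_map`.
#' @param truth A `place_cell` or a 1 mm probability matrix over the same
#'   arena.
#' @return A single non-negative number.
#' @export
mise <- function(ratemap, truth) {
  stopifnot(inherits(ratemap, "rate_map"))
  f <- truth_surface(truth)
  r1 <- upsample_1mm(ratemap)
  stopifnot(all(dim(r1) == dim(f)))
  supp <- !is.na(r1)
  if (!any(supp)) stop("rate map is fully missing")
  rs <- sum(r1[supp])
  fsum <- sum(f[supp])
  if (fsum <= 0) stop("truth surface has no mass on the map support")
  rn <- if (rs > 0) r1[supp] / rs else r1[supp]
  fn <- f[supp] / fsum
  mean((rn - fn)^2)
}

#' Count firing fields in a map
#'
#' Thresholds the surface at 20% of its maximum value and counts contiguous
#' regions (8-connectivity by default) whose area exceeds 36 cm^2
#' (3600 mm^2); region area is bin count times bin area.  Missing bins are
#' treated as below threshold.
#'
#' @param map A `rate_map`, or a numeric matrix with `h` giving its bin
#'   size.
#' @param h Bin side length in mm (ignored when `map` is a `rate_map`).
#' @param min_area Minimum field area in mm^2.
#' @param conn Pixel connectivity, 4 or 8.
#' @return Integer field count.
#' @export
detect_fields <- function(map, h = 1, min_area = 3600, conn = 8) {
  if (inherits(map, "rate_map")) {
    h <- map$grid$h
    map <- map$rate
  }
  stopifnot(is.matrix(map), conn %in% c(4, 8))
  if (all(is.na(map))) stop("map is fully missing")
  mx <- max(map, na.rm = TRUE)
  if (mx <= 0) return(0L)   # a silent map has no fields
  mask <- !is.na(map) & map >= 0.2 * mx
  lab <- label_components_cpp(mask, as.integer(conn))
  if (max(lab) == 0) return(0L)
  areas <- tabulate(lab[lab > 0]) * h^2
  sum(areas > min_area)
}

#' Place-field detection error
#'
#' Absolute difference between the number of fields detected in a firing
#' rate map and in the ground-truth probability surface sampled at 1 mm.
#'
#' @inheritParams mise
#' @param truth_fields Optional precomputed field count of the truth
#'   surface (avoids re-labelling the 1 mm surface in sweeps).
#' @return Non-negative integer.
#' @export
field_detect_error <- function(ratemap, truth, truth_fields = NULL) {
  if (is.null(truth_fields))
    truth_fields <- detect_fields(truth_surface(truth), h = 1)
  abs(detect_fields(ratemap) - truth_fields)
}

#' Proportion of empty (missing) bins
#'
#' Number of missing bins (NA, not counting zero-rate bins) divided by the
#' total number of bins.
#'
#' @param ratemap A `rate_map`.
#' @return Fraction in `[0, 1]`.
#' @export
empty_proportion <- function(ratemap) {
  stopifnot(inherits(ratemap, "rate_map"))
  mean(is.na(ratemap$rate))
}

#' Alternative map error metrics
#'
#' Pearson correlation and Euclidean distance between the unit-sum
#' normalized rate map and truth surface, computed on the same jointly
#' non-missing 1 mm support as [mise()].
#'
#' @inheritParams mise
#' @return A list with `pearson_r` and `euclidean`.
#' @export
alt_metrics <- function(ratemap, truth) {
  f <- truth_surface(truth)
  r1 <- upsample_1mm(ratemap)
  supp <- !is.na(r1)
  if (!any(supp)) stop("rate map is fully missing")
  rn <- r1[supp] / sum(r1[supp])
  fn <- f[supp] / sum(f[supp])
  list(pearson_r = if (sd(rn) > 0 && sd(fn) > 0) cor(rn, fn) else NA_real_,
       euclidean = sqrt(sum((rn - fn)^2)))
}

# Per-map-bin aggregates of a 1 mm truth surface: cell count (A), sum (F1)
# and sum of squares (F2) of the truth over the 1 mm cells of each bin.
# Lets sweeps evaluate the exact MISE of many maps on one geometry without
# re-expanding the 1 mm lattice each time.
truth_bin_agg <- function(f, grid) {
  W <- nrow(f)
  H <- ncol(f)
  pi_ <- pmin(pmax(bin_index(seq_len(W) - 0.5, grid$x0, grid$h, grid$nx),
                   1L), grid$nx)
  pj <- pmin(pmax(bin_index(seq_len(H) - 0.5, grid$y0, grid$h, grid$ny),
                  1L), grid$ny)
  idx <- rep(pi_, times = H) + grid$nx * (rep(pj, each = W) - 1L)
  nb <- grid$nx * grid$ny
  fv <- as.vector(f)
  A <- tabulate(idx, nbins = nb)
  F1 <- F2 <- numeric(nb)
  s1 <- rowsum(fv, idx)
  F1[as.integer(rownames(s1))] <- s1
  s2 <- rowsum(fv^2, idx)
  F2[as.integer(rownames(s2))] <- s2
  list(A = A, F1 = F1, F2 = F2)
}

# MISE of a binned rate vector (length nx*ny, NA = missing) against an
# aggregated truth; algebraically identical to mise() on the same inputs.
mise_from_agg <- function(rate_vec, agg) {
  supp <- !is.na(rate_vec) & agg$A > 0
  if (!any(supp)) stop("rate map is fully missing")
  rsum <- sum(agg$A[supp] * rate_vec[supp])
  fsum <- sum(agg$F1[supp])
  rn <- if (rsum > 0) rate_vec[supp] / rsum else rate_vec[supp]
  sum(agg$A[supp] * rn^2 - 2 * rn * agg$F1[supp] / fsum +
        agg$F2[supp] / fsum^2) / sum(agg$A[supp])
}

#' Full error report for one rate map
#'
#' Bundles the objectives used by the parameter optimizer.
#'
#' @inheritParams mise
#' @param compute_time Optional wall-clock construction time (s) recorded by
#'   the caller.
#' @param truth_fields Optional precomputed truth field count.
#' @return A one-row data frame: `mise`, `field_detect_error`,
#'   `empty_proportion`, `compute_time`.
#' @export
error_report <- function(ratemap, truth, compute_time = NA_real_,
                         truth_fields = NULL) {
  data.frame(mise = mise(ratemap, truth),
             field_detect_error = field_detect_error(ratemap, truth,
                                                     truth_fields),
             empty_proportion = empty_proportion(ratemap),
             compute_time = compute_time)
}
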