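#' Bin position and spike data onto a map grid
#'
#' Exact crosstabulation of position samples and spikes into the square bins
#' of a [map_grid()].  Bins are left-closed right-open; points exactly on
#' the top/right grid edge are assigned to the last bin.  Dwell time is the
#' position count multiplied by the sampling interval, so total dwell equals
#' `n_samples / sample_rate` and total spike count equals `n_spikes`
#' exactly.
#'
#' @param traj A `trajectory`.
#' @param spikes A `spike_train` (may be NULL to bin positions only).
#' @param grid A [map_grid()].
#' @return An object of class `binned_session`: matrices `pos_counts`,
#'   `spike_counts` and `dwell` (seconds), all `nx` x `ny` with rows
#'   indexing x, plus `grid` and `fs`.
#' @examples
#' a <- arena_spec()
#' tr <- simulate_random_walk(a, duration = 5, seed = 1)
#' b <- bin_data(tr, NULL, map_grid(a, 100))
#' sum(b$dwell)  # 5 seconds
#' @export
bin_data <- function(traj, spikes, grid) {
  stopifnot(inherits(traj, "trajectory"), inherits(grid, "map_grid"))
  if (length(traj$t) == 0) stop("empty trajectory")
  fs <- 1 / traj$arena$sample_rate
  pc <- bin_counts(traj$x, traj$y, grid)
  sc <- if (is.null(spikes)) matrix(0, grid$nx, grid$ny) else
    bin_counts(spikes$spike_x, spikes$spike_y, grid)
  structure(list(pos_counts = pc, spike_counts = sc, dwell = pc * fs,
                 grid = grid, fs = fs),
            class = "binned_session")
}

bin_counts <- function(x, y, grid) {
  ix <- bin_index(x, grid$x0, grid$h, grid$nx)
  iy <- bin_index(y, grid$y0, grid$h, grid$ny)
  ok <- ix >= 1L & ix <= grid$nx & iy >= 1L & iy <= grid$ny
  m <- matrix(0, grid$nx, grid$ny)
  if (any(ok)) {
    tb <- tabulate(ix[ok] + grid$nx * (iy[ok] - 1L), nbins = grid$nx * grid$ny)
    m[] <- tb
  }
  m
}

new_rate_map <- function(rate, grid, method, params = list()) {
  structure(list(rate = rate, grid = grid, method = method, params = params),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  v <- x$rate[!is.na(x$rate)]
  cat(sprintf(
    "<rate_map> method '%s', %d x %d bins of %g mm, %.1f%% empty, peak %.2f Hz\n",
    x$method, x$grid$nx, x$grid$ny, x$grid$h,
    100 * mean(is.na(x$rate)), if (length(v)) max(v) else NA_real_))
  invisible(x)
}

#' @export
as.matrix.rate_map <- function(x, ...) x$rate
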