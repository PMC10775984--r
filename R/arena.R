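#' Arena specification
#'
#' Describes the recording environment: a rectangular open-field arena with
#' its lower-left corner at the origin, all lengths in millimetres.  The
#' default reproduces a 1.2 m x 1.2 m square arena sampled at 50 Hz, with a
#' 5 mm occupancy/probability grid used by the trajectory simulator.
#'
#' @param width,height Arena side lengths in mm.
#' @param grid_resolution Pixel size (mm) of the binary grid map used for
#'   occupancy bookkeeping and spike-probability surfaces' parent grid during
#'   trajectory simulation.
#' @param sample_rate Positional sampling rate in Hz.
#' @return An object of class `arena_spec`.
#' @examples
#' arena_spec()
#' @export
arena_spec <- function(width = 1200, height = 1200, grid_resolution = 5,
                       sample_rate = 50) {
  stopifnot(is.finite(width), width > 0, is.finite(height), height > 0,
            is.finite(grid_resolution), grid_resolution > 0,
            is.finite(sample_rate), sample_rate > 0)
  structure(list(width = width, height = height,
                 grid_resolution = grid_resolution,
                 sample_rate = sample_rate),
            class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %g x %g mm, %g Hz sampling, %g mm grid\n",
              x$width, x$height, x$sample_rate, x$grid_resolution))
  invisible(x)
}

#' Map grid geometry
#'
#' Defines the square binning lattice used by the histogram-family methods
#' and as the query lattice of the kernel estimators.  The grid is centred on
#' the arena: `nx = ceiling(width / h)` bins span the x extent symmetrically
#' (and likewise in y), so the arena midpoint always coincides with the grid
#' midpoint regardless of bin size.  Bin `(i, j)` covers the left-closed
#' right-open interval `[x0 + i h, x0 + (i+1) h) x [y0 + j h, y0 + (j+1) h)`.
#'
#' @param arena An [arena_spec()].
#' @param h Bin side length in mm.
#' @return An object of class `map_grid` with fields `x0`, `y0`, `h`, `nx`,
#'   `ny`.
#' @examples
#' map_grid(arena_spec(), 50)
#' @export
map_grid <- function(arena, h) {
  stopifnot(inherits(arena, "arena_spec"), is.finite(h), h > 0)
  nx <- ceiling(arena$width / h)
  ny <- ceiling(arena$height / h)
  structure(list(x0 = arena$width / 2 - nx * h / 2,
                 y0 = arena$height / 2 - ny * h / 2,
                 h = h, nx = nx, ny = ny, arena = arena),
            class = "map_grid")
}

#' @export
print.map_grid <- function(x, ...) {
  cat(sprintf("<map_grid> %d x %d bins of %g mm, origin (%g, %g)\n",
              x$nx, x$ny, x$h, x$x0, x$y0))
  invisible(x)
}

# Bin index along one axis; left-closed right-open, points exactly on the
# final (maximum) edge are assigned to the last bin.
bin_index <- function(v, v0, h, n) {
  i <- floor((v - v0) / h) + 1L
  i[i > n & v <= v0 + n * h] <- n
  i
}

# Bin centre coordinates along x / y
grid_centers_x <- function(grid) grid$x0 + (seq_len(grid$nx) - 0.5) * grid$h
grid_centers_y <- function(grid) grid$y0 + (seq_len(grid$ny) - 0.5) * grid$h
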