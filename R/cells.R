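#' Generate a pool of firing field parameters
#'
#' Draws candidate place-field covariance parameters for one field-size
#' group.  Per-axis variances are drawn independently as
#' `N(group mean, 1000^2)` and clipped below at 1000 mm^2; the xy covariance
#' is the mean of the two variances multiplied by a `N(0, 0.25^2)` draw
#' clipped to `[-1, 1]` (redrawn if the resulting covariance matrix is not
#' positive definite).  Field centroids are uniform over the arena.
#'
#' The three size groups use mean variances of 4000, 8000 and 16000 mm^2,
#' i.e. average field radii at 2 standard deviations of 126, 179 and 253 mm.
#'
#' @param arena An [arena_spec()].
#' @param size_group `"small"`, `"medium"` or `"large"`.
#' @param n_fields Number of fields in the pool (512 by default).
#' @param seed Optional integer seed.
#' @return A data frame with one row per field: `cx`, `cy`, `var_x`,
#'   `var_y`, `cov_xy`, `radius` (the field's own 2 SD radius in mm).
#' @export
make_field_pool <- function(arena, size_group = c("small", "medium", "large"),
                            n_fields = 512, seed = NULL) {
  size_group <- match.arg(size_group)
  if (!is.null(seed))
    return(withr::with_seed(as.integer(seed),
      make_field_pool(arena, size_group, n_fields, seed = NULL)))
  mean_var <- switch(size_group, small = 4000, medium = 8000, large = 16000)
  var_x <- pmax(rnorm(n_fields, mean_var, 1000), 1000)
  var_y <- pmax(rnorm(n_fields, mean_var, 1000), 1000)
  cov_xy <- numeric(n_fields)
  for (i in seq_len(n_fields)) {
    mv <- (var_x[i] + var_y[i]) / 2
    repeat {
      m <- pmin(pmax(rnorm(1, 0, 0.25), -1), 1)
      cv <- mv * m
      if (var_x[i] * var_y[i] - cv^2 > 0) break   # keep matrix PD
    }
    cov_xy[i] <- cv
  }
  data.frame(cx = runif(n_fields, 0, arena$width),
             cy = runif(n_fields, 0, arena$height),
             var_x = var_x, var_y = var_y, cov_xy = cov_xy,
             radius = 2 * sqrt((var_x + var_y) / 2))
}

#' Average field radius (2 SD) of a field-size group
#'
#' The nominal radius at two standard deviations implied by a group's mean
#' per-axis variance: `2 * sqrt(mean variance)`.
#'
#' @param size_group `"small"`, `"medium"` or `"large"`, or a numeric mean
#'   variance in mm^2.
#' @return Radius in mm.
#' @examples
#' sapply(c("small", "medium", "large"), group_field_radius)
#' @export
group_field_radius <- function(size_group) {
  v <- if (is.numeric(size_group)) size_group else
    switch(match.arg(size_group, c("small", "medium", "large")),
           small = 4000, medium = 8000, large = 16000)
  2 * sqrt(v)
}

# Unit-peak bivariate Gaussian surface of one field evaluated on the 1 mm
# cell-centre lattice of the arena (rows = x, cols = y).
field_surface <- function(field, arena, res = 1) {
  xs <- (seq_len(round(arena$width / res)) - 0.5) * res
  ys <- (seq_len(round(arena$height / res)) - 0.5) * res
  dx <- xs - field$cx
  dy <- ys - field$cy
  det <- field$var_x * field$var_y - field$cov_xy^2
  a <- field$var_y / det
  b <- -field$cov_xy / det
  c_ <- field$var_x / det
  q <- a * dx^2 %o% rep(1, length(dy)) +
    2 * b * dx %o% dy +
    c_ * rep(1, length(dx)) %o% dy^2
  exp(-q / 2)
}

#' Simulate a place cell
#'
#' Builds a ground-truth spike-probability surface for one simulated place
#' cell.  The number of fields is drawn from a gamma distribution (shape
#' 5.73, scale 0.26), clipped above 1 and rounded to an integer; that many
#' fields are sampled from `field_pool` and merged by taking the pointwise
#' maximum of their unit-peak Gaussian surfaces.  The surface is evaluated on
#' a 1 mm grid over the arena, so the value at a position is the spike
#' probability per position sample.  The cell's target mean firing rate is
#' drawn as `N(1, 1)` Hz clipped to `[0.5, 10]`.
#'
#' @param arena An [arena_spec()].
#' @param size_group Field-size group; used only when `field_pool` is NULL.
#' @param field_pool A data frame from [make_field_pool()]; generated on the
#'   fly (with the same seed stream) when NULL.
#' @param seed Optional integer seed.
#' @return An object of class `place_cell` with elements `fields` (data
#'   frame), `prob_map` (matrix, rows = x at 1 mm), `mean_rate`, `n_fields`,
#'   `true_radius` (mean 2 SD field radius, mm) and `arena`.
#' @export
simulate_place_cell <- function(arena, size_group = c("small", "medium", "large"),
                                field_pool = NULL, seed = NULL) {
  size_group <- match.arg(size_group)
  if (!is.null(seed))
    return(withr::with_seed(as.integer(seed),
      simulate_place_cell(arena, size_group, field_pool, seed = NULL)))
  if (is.null(field_pool))
    field_pool <- make_field_pool(arena, size_group)
  if (nrow(field_pool) == 0) stop("field pool is empty")
  nf <- max(1L, round(max(rgamma(1, shape = 5.73, scale = 0.26), 1)))
  sel <- field_pool[sample.int(nrow(field_pool), nf, replace = nf > nrow(field_pool)), ,
                    drop = FALSE]
  prob <- NULL
  for (i in seq_len(nrow(sel))) {
    s <- field_surface(sel[i, ], arena)
    prob <- if (is.null(prob)) s else pmax(prob, s)
  }
  mean_rate <- pmin(pmax(rnorm(1, 1, 1), 0.5), 10)
  structure(list(fields = sel, prob_map = prob, mean_rate = mean_rate,
                 n_fields = nrow(sel), true_radius = mean(sel$radius),
                 arena = arena, size_group = size_group),
            class = "place_cell")
}

#' @export
print.place_cell <- function(x, ...) {
  cat(sprintf(
    "<place_cell> %d field(s), mean 2SD radius %.0f mm, target rate %.2f Hz\n",
    x$n_fields, x$true_radius, x$mean_rate))
  invisible(x)
}
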