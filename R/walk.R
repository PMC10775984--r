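#' Random walk configuration
#'
#' Parameters of the open-field Gaussian random walk used to emulate rodent
#' foraging.  The walk advances in 1 s decision steps on a coarse grid map of
#' the arena (pixel size `arena$grid_resolution`, 5 mm by default); at each
#' step the next position is the pixel maximising a sum of weighted terms:
#' a Gaussian over step distance, a von Mises heading-persistence term, the
#' inverted recent occupancy (a retrospective sliding window), a wall term,
#' a centre-attraction term, and an optional goal bias.  Distance-like
#' quantities (`step_mu`, `step_sigma`, `center_sigma`, `wall_sigma`,
#' `goal_sigma`, `thigmotaxis_wall_sigma`) are expressed in grid pixels.
#'
#' With the default 5 mm pixels, `step_mu = 64` corresponds to a preferred
#' step of 320 mm per second, i.e. a 32 cm/s running speed.
#'
#' @param step_mu,step_sigma Mean and SD (grid pixels) of the Gaussian step
#'   distance term.
#' @param vonmises_kappa Concentration of the von Mises heading term.
#' @param occupancy_window Length (s) of the retrospective occupancy window.
#' @param occupancy_footprint Radius (mm) of the disc stamped into the
#'   occupancy map around each position sample; a rat samples a body-width
#'   swath, not a line, and with a pointwise footprint the inverted-occupancy
#'   term degenerates into a tight perimeter spiral.
#' @param wall_sigma SD (mm) of the Gaussian weighting of
#'   distance-to-nearest-wall.
#' @param center_sigma SD (grid pixels) of the Gaussian weighting of
#'   distance-to-centre; the default is nearly flat over the arena, as wall
#'   repulsion in a convex arena already implies a weak centre attraction.
#' @param bias_mode One of `"uniform"`, `"goal"`, `"thigmotaxis"`.  In
#'   uniform and goal modes the wall weight is inverted so that the agent is
#'   weakly repelled by walls and weakly attracted to the centre; in
#'   thigmotaxis mode the centre term is disabled and the (narrower) wall
#'   weight left uninverted so the agent hugs the walls.
#' @param goal_sigma SD (grid pixels) of the goal bias term.
#' @param goal_downweight Multiplier applied to the goal term.
#' @param thigmotaxis_wall_sigma Wall sigma (mm-scale, as `wall_sigma`) used
#'   in thigmotaxis mode.
#' @param jitter_max Half-range (mm) of the uniform tracking jitter added to
#'   each coordinate.
#' @param path_smoothing Scalar roughness penalty of the penalized-spline
#'   (Whittaker) smoother applied to the jittered path.
#' @param upsample_factor Position samples generated per decision step
#'   (50 for a 50 Hz sampling rate).
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return An object of class `random_walk_config`.
#' @export
random_walk_config <- function(step_mu = 64, step_sigma = 128,
                               vonmises_kappa = 1, occupancy_window = 480,
                               occupancy_footprint = 40,
                               center_sigma = 512, wall_sigma = 512,
                               bias_mode = c("uniform", "goal", "thigmotaxis"),
                               goal_sigma = 25, goal_downweight = 0.9,
                               thigmotaxis_wall_sigma = 100,
                               jitter_max = 85, path_smoothing = 128,
                               upsample_factor = 50, seed = NULL) {
  bias_mode <- match.arg(bias_mode)
  cfg <- list(step_mu = step_mu, step_sigma = step_sigma,
              vonmises_kappa = vonmises_kappa,
              occupancy_window = occupancy_window,
              occupancy_footprint = occupancy_footprint,
              center_sigma = center_sigma, wall_sigma = wall_sigma,
              bias_mode = bias_mode, goal_sigma = goal_sigma,
              goal_downweight = goal_downweight,
              thigmotaxis_wall_sigma = thigmotaxis_wall_sigma,
              jitter_max = jitter_max, path_smoothing = path_smoothing,
              upsample_factor = as.integer(upsample_factor), seed = seed)
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  if (any(!is.finite(num)))
    stop("random walk configuration contains non-finite values")
  stopifnot(step_sigma > 0, center_sigma > 0, wall_sigma > 0, goal_sigma > 0,
            thigmotaxis_wall_sigma > 0, upsample_factor >= 1,
            occupancy_window > 0, occupancy_footprint >= 0)
  structure(cfg, class = "random_walk_config")
}

new_trajectory <- function(t, x, y, arena) {
  structure(list(t = t, x = x, y = y,
                 duration = length(t) / arena$sample_rate, arena = arena),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples, %.1f s at %g Hz, arena %g x %g mm\n",
              length(x$t), x$duration, x$arena$sample_rate,
              x$arena$width, x$arena$height))
  invisible(x)
}

# Whittaker second-difference penalized smoother with optional bisquare
# robust reweighting; the discrete analogue of penalized-spline smoothing
# with a single scalar penalty.
whittaker_smooth <- function(y, lambda, robust_iter = 2) {
  n <- length(y)
  if (n < 3 || lambda <= 0) return(y)
  D2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                            rep(1, n - 2)))
  DtD <- Matrix::crossprod(D2)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(robust_iter + 1)) {
    A <- Matrix::Diagonal(n, w) + lambda * DtD
    z <- as.numeric(Matrix::solve(A, w * y))
    if (it > robust_iter) break
    r <- y - z
    s <- stats::mad(r)
    if (!is.finite(s) || s <= 0) break
    u <- abs(r) / (6 * s)
    w <- ifelse(u < 1, (1 - u^2)^2, 0)
    if (all(w == 0)) { w <- rep(1, n) }
  }
  z
}

#' Simulate an open-field random walk trajectory
#'
#' Generates a uniformly sampled `(t, x, y)` trajectory emulating a rodent
#' foraging in a rectangular arena.  The agent starts at the arena centre
#' with a random heading and takes 1 s decision steps, each chosen as the
#' argmax of the summed, max-normalized decision terms described in
#' [random_walk_config()].  Straight-line interpolation between decision
#' points (upsampled by `config$upsample_factor`) yields the position
#' samples; uniform tracking jitter is then added, the path is smoothed with
#' a robust penalized spline, and samples are clamped to the arena bounds.
#'
#' @param arena An [arena_spec()].
#' @param config A [random_walk_config()].
#' @param duration Walk duration in seconds (at least one 1 s decision step).
#' @param seed Optional integer seed overriding `config$seed`.
#' @return A `trajectory` object with fields `t`, `x`, `y`, `duration`,
#'   `arena`.
#' @examples
#' traj <- simulate_random_walk(arena_spec(), random_walk_config(),
#'                              duration = 10, seed = 1)
#' range(traj$x)
#' @export
simulate_random_walk <- function(arena, config = random_walk_config(),
                                 duration, seed = NULL) {
  stopifnot(inherits(arena, "arena_spec"),
            inherits(config, "random_walk_config"))
  if (!is.finite(duration) || duration < 1)
    stop("duration must cover at least one 1 s decision step")
  seed <- if (is.null(seed)) config$seed else seed
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
                            random_walk_impl(arena, config, duration)))
  }
  random_walk_impl(arena, config, duration)
}

random_walk_impl <- function(arena, config, duration) {
  res <- arena$grid_resolution
  nxp <- max(1L, round(arena$width / res))
  nyp <- max(1L, round(arena$height / res))
  px <- (seq_len(nxp) - 0.5) * res            # pixel centres, mm
  py <- (seq_len(nyp) - 0.5) * res
  PX <- rep(px, times = nyp)
  PY <- rep(py, each = nxp)
  npix <- nxp * nyp

  # static decision terms; wall distances weighted on the mm scale (a
  # pixel-scale sigma of 512 would be flat over the arena and the stated
  # wall repulsion would vanish), centre distances on the pixel scale
  gauss <- function(d, mu, sigma) exp(-((d - mu)^2) / (2 * sigma^2))
  dwall_mm <- pmin(PX, arena$width - PX, PY, arena$height - PY)
  dcent_px <- sqrt((PX - arena$width / 2)^2 +
                     (PY - arena$height / 2)^2) / res
  if (config$bias_mode == "thigmotaxis") {
    wall_term <- gauss(dwall_mm, 0, config$thigmotaxis_wall_sigma)
    wall_term <- wall_term / max(wall_term)       # attracted to walls
    cent_term <- rep(0, npix)
  } else {
    wall_term <- gauss(dwall_mm, 0, config$wall_sigma)
    wall_term <- 1 - wall_term / max(wall_term)   # repelled by walls
    cent_term <- gauss(dcent_px, 0, config$center_sigma)
    cent_term <- cent_term / max(cent_term)       # attracted to centre
  }
  goal_term <- NULL
  if (config$bias_mode == "goal") {
    gx <- 0.75 * arena$width
    gy <- 0.5 * arena$height
    dgoal <- sqrt((PX - gx)^2 + (PY - gy)^2) / res
    goal_term <- gauss(dgoal, 0, config$goal_sigma)
    goal_term <- config$goal_downweight * goal_term / max(goal_term)
  }
  # disc of pixel offsets stamped into the occupancy map around each sample
  fr <- ceiling(config$occupancy_footprint / res)
  foot <- expand.grid(dx = -fr:fr, dy = -fr:fr)
  foot <- foot[foot$dx^2 + foot$dy^2 <= fr^2, ]

  n_steps <- floor(duration)
  u <- config$upsample_factor
  heading <- runif(1, -pi, pi)
  cx <- arena$width / 2
  cy <- arena$height / 2
  occ <- numeric(npix)
  occ_hist <- vector("list", n_steps)
  xs <- numeric(n_steps * u)
  ys <- numeric(n_steps * u)
  frac <- seq_len(u) / u
  sfrac <- seq_len(10) / 10
  win_steps <- max(1L, round(config$occupancy_window))

  for (s in seq_len(n_steps)) {
    D <- sqrt((PX - cx)^2 + (PY - cy)^2) / res
    step_term <- gauss(D, config$step_mu, config$step_sigma)
    step_term <- step_term / max(step_term)
    A <- atan2(PY - cy, PX - cx)
    # already normalized: the von Mises density peaks at cos = 1
    vm_term <- exp(config$vonmises_kappa * (cos(A - heading) - 1))
    occ_term <- if (max(occ) > 0) 1 - occ / max(occ) else rep(1, npix)
    w <- step_term + vm_term + occ_term + wall_term + cent_term
    if (!is.null(goal_term)) w <- w + goal_term
    w[D == 0] <- -Inf   # a step must move; heading is undefined in place
    k <- which.max(w)
    nx_ <- PX[k]
    ny_ <- PY[k]
    i0 <- (s - 1) * u
    xs[i0 + seq_len(u)] <- cx + frac * (nx_ - cx)
    ys[i0 + seq_len(u)] <- cy + frac * (ny_ - cy)
    heading <- atan2(ny_ - cy, nx_ - cx)
    # occupancy along this step's path, footprint-dilated, sliding window
    ix <- pmin(pmax(ceiling((cx + sfrac * (nx_ - cx)) / res), 1L), nxp)
    iy <- pmin(pmax(ceiling((cy + sfrac * (ny_ - cy)) / res), 1L), nyp)
    sx <- pmin(pmax(rep(ix, each = nrow(foot)) + foot$dx, 1L), nxp)
    sy <- pmin(pmax(rep(iy, each = nrow(foot)) + foot$dy, 1L), nyp)
    idx <- unique(sx + nxp * (sy - 1L))
    occ_hist[[s]] <- idx
    occ[idx] <- occ[idx] + 1
    if (s > win_steps) {
      old <- occ_hist[[s - win_steps]]
      occ[old] <- occ[old] - 1
      occ_hist[s - win_steps] <- list(NULL)
    }
    cx <- nx_
    cy <- ny_
  }

  n <- n_steps * u
  xs <- xs + runif(n, -config$jitter_max, config$jitter_max)
  ys <- ys + runif(n, -config$jitter_max, config$jitter_max)
  xs <- whittaker_smooth(xs, config$path_smoothing)
  ys <- whittaker_smooth(ys, config$path_smoothing)
  xs <- pmin(pmax(xs, 0), arena$width)
  ys <- pmin(pmax(ys, 0), arena$height)
  tt <- (seq_len(n) - 1) / arena$sample_rate
  new_trajectory(tt, xs, ys, arena)
}

#' Clip a trajectory to a shorter duration
#'
#' Retains the first `duration * sample_rate` samples; timestamps are kept
#' as-is so a clipped trajectory is an exact prefix of its parent.
#'
#' @param traj A `trajectory`.
#' @param duration Target duration in seconds; must not exceed
#'   `traj$duration`.
#' @return A `trajectory`.
#' @export
clip_trajectory <- function(traj, duration) {
  stopifnot(inherits(traj, "trajectory"))
  if (duration > traj$duration + 1e-9)
    stop("cannot clip to a duration longer than the trajectory")
  n <- round(duration * traj$arena$sample_rate)
  new_trajectory(traj$t[seq_len(n)], traj$x[seq_len(n)], traj$y[seq_len(n)],
                 traj$arena)
}
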