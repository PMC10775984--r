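#' Simulate a spike train from a place cell and a trajectory
#'
#' Converts a cell's spike-probability surface into spikes along a
#' trajectory.  For every position sample the probability value is looked up
#' on the 1 mm surface; to emulate tracking error and theta-related drift,
#' each sample instead reads the probability from a time-shifted point on
#' the trajectory, the shift drawn as `N(jitter_mu, jitter_sigma)` seconds
#' with random sign.  A per-sample spike count is drawn from
#' `Poisson(probability)` plus an independent `Poisson(background_lambda)`
#' background.  With `overdispersion = TRUE` the probability vector is first
#' multiplied by a 1.5 Hz oscillation ranging from 0.2 to 1.8 (mean 1).
#' Finally spikes are uniformly downsampled (without replacement) so the
#' realized mean rate matches `cell$mean_rate`; if fewer raw spikes are
#' available than the target a warning is issued and all spikes are kept.
#'
#' @param cell A [simulate_place_cell()] object.
#' @param traj A `trajectory` within the same arena.
#' @param background_lambda Background (out-of-field) Poisson rate per
#'   sample.
#' @param jitter_mu,jitter_sigma Mean and SD (s) of the unsigned temporal
#'   jitter.
#' @param overdispersion Add slow multiplicative rate modulation.
#' @param seed Optional integer seed.
#' @return An object of class `spike_train`: `spike_t`, `spike_x`,
#'   `spike_y`, `n_spikes`, `duration`.
#' @export
simulate_spikes <- function(cell, traj, background_lambda = 0.001,
                            jitter_mu = 0.01, jitter_sigma = 0.02,
                            overdispersion = FALSE, seed = NULL) {
  stopifnot(inherits(cell, "place_cell"), inherits(traj, "trajectory"))
  if (!is.null(seed))
    return(withr::with_seed(as.integer(seed),
      simulate_spikes(cell, traj, background_lambda, jitter_mu, jitter_sigma,
                      overdispersion, seed = NULL)))
  arena <- traj$arena
  n <- length(traj$t)
  fs <- 1 / arena$sample_rate

  ix <- pmin(pmax(ceiling(traj$x), 1L), nrow(cell$prob_map))
  iy <- pmin(pmax(ceiling(traj$y), 1L), ncol(cell$prob_map))
  p <- cell$prob_map[cbind(ix, iy)]
  # temporal jitter: read the probability from a shifted sample index
  shift <- round(sample(c(-1, 1), n, replace = TRUE) *
                   rnorm(n, jitter_mu, jitter_sigma) / fs)
  src <- pmin(pmax(seq_len(n) + shift, 1L), n)
  p <- p[src]
  if (overdispersion)
    p <- p * (1 + 0.8 * sin(2 * pi * 1.5 * traj$t))
  counts <- rpois(n, p) + rpois(n, background_lambda)

  spike_idx <- rep.int(seq_len(n), counts)
  n_raw <- length(spike_idx)
  target <- floor(cell$mean_rate * traj$duration)
  if (n_raw > target) {
    keep <- sort(sample.int(n_raw, target))
    spike_idx <- spike_idx[keep]
  } else if (n_raw < target) {
    warning(sprintf(
      "only %d raw spikes available for a target of %d; keeping all",
      n_raw, target))
  }
  structure(list(spike_t = traj$t[spike_idx],
                 spike_x = traj$x[spike_idx],
                 spike_y = traj$y[spike_idx],
                 n_spikes = length(spike_idx),
                 duration = traj$duration),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.1f s (%.2f Hz)\n",
              x$n_spikes, x$duration, x$n_spikes / x$duration))
  invisible(x)
}
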