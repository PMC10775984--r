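# Shared fixtures, built once per test run.  A short 4-minute session keeps
# the suite fast while exercising the full simulation pipeline.
fix <- local({
  arena <- arena_spec()
  traj <- simulate_random_walk(arena, random_walk_config(), 240, seed = 11)
  cell <- simulate_place_cell(arena, "medium", seed = 12)
  spikes <- suppressWarnings(simulate_spikes(cell, traj, seed = 13))
  list(arena = arena, traj = traj, cell = cell, spikes = spikes)
})

# 16-minute session for checks whose published claims are stated at that
# duration (adaptive pixelwise-vs-convolution agreement)
fix16 <- local({
  traj <- simulate_random_walk(fix$arena, random_walk_config(), 960,
                               seed = 14)
  spikes <- suppressWarnings(simulate_spikes(fix$cell, traj, seed = 15))
  list(traj = traj, spikes = spikes)
})

# Hand-built trajectory / spike-train objects for exact arithmetic tests
toy_traj <- function(x, y, arena = arena_spec()) {
  ratemapr:::new_trajectory((seq_along(x) - 1) / arena$sample_rate, x, y,
                            arena)
}

toy_spikes <- function(x, y, t = NULL, duration = NULL) {
  structure(list(spike_t = if (is.null(t)) seq_along(x) * 0 else t,
                 spike_x = x, spike_y = y, n_spikes = length(x),
                 duration = duration %||% max(1, length(x) * 0.02)),
            class = "spike_train")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# place cell with a constant spike probability everywhere (uniform firing)
const_cell <- function(p, mean_rate = 10, arena = arena_spec()) {
  structure(list(fields = data.frame(), n_fields = 1L,
                 prob_map = matrix(p, round(arena$width),
                                   round(arena$height)),
                 mean_rate = mean_rate, true_radius = NA_real_,
                 arena = arena, size_group = "uniform"),
            class = "place_cell")
}
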