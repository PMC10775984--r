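#' Write a session (trajectory + spikes) as delimited text
#'
#' Positions go to `pos.csv` (columns `t`, `x`, `y`) and spikes to
#' `spikes.csv` (columns `spike_t`, `spike_x`, `spike_y`), each preceded by
#' a `#` comment line declaring the units (seconds and millimetres) and the
#' sampling rate.
#'
#' @param traj A `trajectory`.
#' @param spikes A `spike_train` (optional).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_session <- function(traj, spikes = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # %.17g guarantees doubles survive the text round trip bit-for-bit
  write_cols <- function(df, header, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(paste(names(df), collapse = ","), con)
    if (nrow(df))
      writeLines(do.call(paste, c(lapply(df, function(v) sprintf("%.17g", v)),
                                  sep = ",")), con)
  }
  pos_path <- file.path(dir, "pos.csv")
  write_cols(data.frame(t = traj$t, x = traj$x, y = traj$y),
             sprintf("# units: t s, x mm, y mm; sample_rate %g Hz; arena %g x %g mm",
                     traj$arena$sample_rate, traj$arena$width,
                     traj$arena$height), pos_path)
  paths <- pos_path
  if (!is.null(spikes)) {
    spk_path <- file.path(dir, "spikes.csv")
    write_cols(data.frame(spike_t = spikes$spike_t,
                          spike_x = spikes$spike_x,
                          spike_y = spikes$spike_y),
               "# units: spike_t s, spike_x mm, spike_y mm", spk_path)
    paths <- c(paths, spk_path)
  }
  invisible(paths)
}

#' Read a session from delimited text
#'
#' Parses and validates the files written by [write_session()].  Rows are
#' sorted by time; duplicate position timestamps, missing columns and
#' non-finite coordinates are rejected with descriptive errors.
#'
#' @param dir Directory containing `pos.csv` and optionally `spikes.csv`,
#'   or the path of the position file itself.
#' @param arena An [arena_spec()]; the sample rate is checked against the
#'   median time step.
#' @return A list with `traj` and `spikes` (NULL when absent).
#' @export
read_session <- function(dir, arena = arena_spec()) {
  pos_path <- if (dir.exists(dir)) file.path(dir, "pos.csv") else dir
  if (!file.exists(pos_path)) stop("position file not found: ", pos_path)
  pos <- read.csv(pos_path, comment.char = "#")
  need <- c("t", "x", "y")
  if (!all(need %in% names(pos)))
    stop("position file must have columns t, x, y")
  if (anyNA(pos) || any(!is.finite(as.matrix(pos))))
    stop("position file contains missing or non-finite values")
  pos <- pos[order(pos$t), ]
  if (anyDuplicated(pos$t)) stop("duplicate position timestamps")
  dt <- median(diff(pos$t))
  if (abs(dt * arena$sample_rate - 1) > 1e-6)
    stop(sprintf("time step %g s does not match the %g Hz sample rate",
                 dt, arena$sample_rate))
  traj <- new_trajectory(pos$t, pos$x, pos$y, arena)
  spikes <- NULL
  spk_path <- file.path(dirname(pos_path), "spikes.csv")
  if (file.exists(spk_path)) {
    spk <- read.csv(spk_path, comment.char = "#")
    need <- c("spike_t", "spike_x", "spike_y")
    if (!all(need %in% names(spk)))
      stop("spike file must have columns spike_t, spike_x, spike_y")
    if (nrow(spk) > 0 && (anyNA(spk) || any(!is.finite(as.matrix(spk)))))
      stop("spike file contains missing or non-finite values")
    spk <- spk[order(spk$spike_t), ]
    spikes <- structure(list(spike_t = spk$spike_t, spike_x = spk$spike_x,
                             spike_y = spk$spike_y, n_spikes = nrow(spk),
                             duration = traj$duration),
                        class = "spike_train")
  }
  list(traj = traj, spikes = spikes)
}

#' Write a rate map raster with a JSON sidecar
#'
#' The raster goes to `<path>.csv` (rows = x bins, columns = y bins, NA for
#' missing) and the grid geometry, method and parameters to `<path>.json`.
#'
#' @param ratemap A `rate_map`.
#' @param path Output path stem (without extension).
#' @return Invisibly, the two paths.
#' @export
write_rate_map <- function(ratemap, path) {
  csv <- paste0(path, ".csv")
  js <- paste0(path, ".json")
  write.table(ratemap$rate, csv, sep = ",", row.names = FALSE,
              col.names = FALSE)
  g <- ratemap$grid
  meta <- list(method = ratemap$method,
               params = ratemap$params[!vapply(ratemap$params, is.matrix,
                                               logical(1))],
               units = "Hz",
               grid = list(x0 = g$x0, y0 = g$y0, h = g$h, nx = g$nx,
                           ny = g$ny),
               arena = unclass(g$arena))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Read a rate map written by [write_rate_map()]
#'
#' @param path Path stem used when writing.
#' @return A `rate_map`.
#' @export
read_rate_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rate <- as.matrix(read.csv(paste0(path, ".csv"), header = FALSE))
  dimnames(rate) <- NULL
  arena <- do.call(arena_spec, as.list(meta$arena))
  grid <- structure(c(meta$grid, list(arena = arena)), class = "map_grid")
  new_rate_map(rate, grid, meta$method, as.list(meta$params))
}

#' Generate deterministic fixture sessions
#'
#' Writes a tree of simulated sessions with ground-truth sidecars, for test
#' suites and demos.  Profiles: `"smoke"` is 2 cells recorded for 4
#' minutes; `"paper_small"` is 24 cells across the three field-size groups
#' at 4- and 16-minute durations.
#'
#' @param profile `"smoke"` or `"paper_small"`.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Invisibly, a data frame manifest of the sessions written.
#' @export
make_fixtures <- function(profile = c("smoke", "paper_small"), seed = 1,
                          dir) {
  profile <- match.arg(profile)
  spec <- switch(profile,
    smoke = list(n_cells = 2, durations = 240, groups = "medium",
                 n_traj = 2),
    paper_small = list(n_cells = 24, durations = c(240, 960),
                       groups = c("small", "medium", "large"), n_traj = 8))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (dur in spec$durations) {
    cohort <- simulate_cohort(spec$n_cells, dur, spec$groups,
                              n_traj = spec$n_traj, seed = seed + dur)
    for (i in seq_along(cohort$sessions)) {
      s <- cohort$sessions[[i]]
      sdir <- file.path(dir, sprintf("%s_%03ds_cell%02d", profile, dur, i))
      write_session(cohort$trajectories[[s$traj_id]], s$spikes, sdir)
      truth <- list(fields = s$cell$fields, mean_rate = s$cell$mean_rate,
                    n_fields = s$cell$n_fields,
                    true_radius = s$cell$true_radius,
                    size_group = s$cell$size_group, seed = seed,
                    duration = dur)
      jsonlite::write_json(truth, file.path(sdir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "columns")
      rows[[length(rows) + 1]] <- data.frame(dir = basename(sdir),
                                             duration = dur, cell = i)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Rebuild a place cell's probability surface from a truth sidecar
#'
#' @param path Path of a `truth.json` written by [make_fixtures()].
#' @param arena An [arena_spec()].
#' @return A `place_cell`.
#' @export
read_truth <- function(path, arena = arena_spec()) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- as.data.frame(truth$fields)
  prob <- NULL
  for (i in seq_len(nrow(fields))) {
    s <- field_surface(fields[i, ], arena)
    prob <- if (is.null(prob)) s else pmax(prob, s)
  }
  structure(list(fields = fields, prob_map = prob,
                 mean_rate = truth$mean_rate, n_fields = nrow(fields),
                 true_radius = truth$true_radius, arena = arena,
                 size_group = truth$size_group),
            class = "place_cell")
}

#' Run the simulate / map / evaluate pipeline
#'
#' A small orchestrator over the package functions: simulates fixture
#' sessions (stage `simulate`), builds a rate map per session (stage `map`)
#' and scores each against its ground truth (stage `evaluate`), writing all
#' results under `out_dir`.  A stage whose output already exists is skipped,
#' so re-running with an unchanged configuration is a no-op; deleting one
#' session's map re-creates only that map.
#'
#' @param config A list (or path of a YAML file) with elements `profile`,
#'   `seed`, `method`, `bin_size`, `smoothing`.
#' @param out_dir Output directory.
#' @return Invisibly, the evaluation data frame.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(list(profile = "smoke", seed = 1, method = "histogram",
                         bin_size = 50, smoothing = 50), config)
  arena <- arena_spec()
  sess_dir <- file.path(out_dir, "sessions")
  manifest_path <- file.path(sess_dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    message("[simulate] generating '", cfg$profile, "' fixtures (seed ",
            cfg$seed, ")")
    make_fixtures(cfg$profile, cfg$seed, sess_dir)
  } else message("[simulate] cached")
  manifest <- read.csv(manifest_path)
  map_dir <- file.path(out_dir, "maps")
  dir.create(map_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    sdir <- file.path(sess_dir, basename(manifest$dir[i]))
    stem <- file.path(map_dir, basename(manifest$dir[i]))
    if (!file.exists(paste0(stem, ".csv"))) {
      message("[map] ", basename(sdir))
      sess <- read_session(sdir, arena)
      t0 <- proc.time()[["elapsed"]]
      rm_ <- build_rate_map(sess$traj, sess$spikes, cfg$method,
                            cfg$bin_size, cfg$smoothing)
      rm_$params$compute_time <- proc.time()[["elapsed"]] - t0
      write_rate_map(rm_, stem)
    }
    rm_ <- read_rate_map(stem)
    cell <- read_truth(file.path(sdir, "truth.json"), arena)
    rep_ <- error_report(rm_, cell,
                         compute_time = rm_$params$compute_time %||% NA_real_)
    rows[[i]] <- cbind(session = basename(sdir), rep_)
  }
  ev <- do.call(rbind, rows)
  write.csv(ev, file.path(out_dir, "evaluation.csv"), row.names = FALSE)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE)
  invisible(ev)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
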