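#' Build a rate map by method name
#'
#' Uniform front end over the six estimators, mapping the generic
#' `smoothing` argument onto each method's own parameter: Gaussian sigma
#' (mm) for the histogram, shift count `m` for the ASH, `alpha` for adaptive
#' smoothing, dwell seconds `t` for adaptive binning, bandwidth (mm) for the
#' KSDE and spatial sigma (mm) for the temporal KSDE.
#'
#' @param traj A `trajectory`.
#' @param spikes A `spike_train`.
#' @param method One of `"histogram"`, `"ash"`, `"adaptive_smooth"`,
#'   `"adaptive_bin"`, `"ksde"`, `"tksde"`.
#' @param bin_size Bin (or query grid) side length in mm.
#' @param smoothing Method-specific smoothing value (see Details).
#' @param ... Further arguments passed to the method function.
#' @return A `rate_map`.
#' @export
build_rate_map <- function(traj, spikes, method, bin_size, smoothing, ...) {
  method <- match.arg(method, c("histogram", "ash", "adaptive_smooth",
                                "adaptive_bin", "ksde", "tksde"))
  switch(method,
    histogram = histogram_map(traj, spikes, bin_size, sigma = smoothing, ...),
    ash = ash_map(traj, spikes, bin_size, m = max(1L, round(smoothing)), ...),
    adaptive_smooth = adaptive_smooth_map(traj, spikes, bin_size,
                                          alpha = smoothing, ...),
    adaptive_bin = adaptive_bin_map(traj, spikes, bin_size, t = smoothing, ...),
    ksde = ksde_map(traj, spikes, bin_size, bandwidth = smoothing, ...),
    tksde = tksde_map(traj, spikes, bin_size, sigma = smoothing, ...))
}

#' Simulate a benchmark cohort
#'
#' Generates the session structure of the simulation protocol: `n_traj`
#' random-walk trajectories of the requested duration and `n_cells` place
#' cells spread over the requested size groups, each cell assigned
#' round-robin to a trajectory and converted to spikes.
#'
#' @param n_cells Number of cells.
#' @param duration Session duration in seconds.
#' @param size_groups Character vector of group names to cycle over.
#' @param n_traj Number of distinct trajectories shared by the cohort.
#' @param arena An [arena_spec()].
#' @param overdispersion Passed to [simulate_spikes()].
#' @param bias_mode Passed to [random_walk_config()].
#' @param seed Integer seed; all per-entity seeds derive from it.
#' @return A list with `trajectories` and `sessions`; each session is a list
#'   `cell`, `traj_id`, `spikes`.
#' @export
simulate_cohort <- function(n_cells, duration,
                            size_groups = c("small", "medium", "large"),
                            n_traj = 8, arena = arena_spec(),
                            overdispersion = FALSE, bias_mode = "uniform",
                            seed = 1) {
  seed <- as.integer(seed)
  cfg <- random_walk_config(bias_mode = bias_mode)
  trajectories <- lapply(seq_len(n_traj), function(i)
    simulate_random_walk(arena, cfg, duration, seed = seed + 1000L + i))
  pools <- lapply(unique(size_groups), function(g)
    make_field_pool(arena, g, seed = seed + 2000L + match(g, c("small", "medium", "large"))))
  names(pools) <- unique(size_groups)
  sessions <- lapply(seq_len(n_cells), function(i) {
    g <- size_groups[((i - 1) %% length(size_groups)) + 1]
    cell <- simulate_place_cell(arena, g, field_pool = pools[[g]],
                                seed = seed + 3000L + i)
    tid <- ((i - 1) %% n_traj) + 1
    spikes <- suppressWarnings(
      simulate_spikes(cell, trajectories[[tid]], seed = seed + 4000L + i))
    list(cell = cell, traj_id = tid, spikes = spikes)
  })
  list(trajectories = trajectories, sessions = sessions)
}

#' Sweep a parameter grid for one mapping method
#'
#' Builds rate maps for every (bin size, smoothing) combination and every
#' session, scores each against its cell's ground truth, and averages the
#' objectives per combination.  A failed individual map is recorded as a
#' missing cell entry rather than aborting the sweep.
#'
#' With `fast = TRUE` the adaptive estimators resolve all smoothing values
#' of a bin size in a single expanding-radius pass per session (the rates
#' are identical); per-combination computation time is then not measured.
#'
#' @param method Method name as in [build_rate_map()].
#' @param cohort A [simulate_cohort()] result.
#' @param bin_sizes,smoothings Numeric parameter axes.
#' @param time_reps Repeated builds whose median is the recorded
#'   computation time (ignored when `fast = TRUE`).
#' @param fast Use the stacked adaptive path without timing.
#' @return A `sweep_result` data frame: one row per combination with the
#'   averaged objectives.
#' @export
sweep_method <- function(method, cohort, bin_sizes, smoothings,
                         time_reps = 3, fast = FALSE) {
  sessions <- cohort$sessions
  truth_fields <- vapply(sessions, function(s)
    detect_fields(s$cell$prob_map, h = 1), integer(1))
  combos <- expand.grid(bin_size = bin_sizes, smoothing = smoothings)
  acc <- matrix(0, nrow(combos), 4,
                dimnames = list(NULL, c("mise", "field_detect_error",
                                        "empty_proportion", "compute_time")))
  nok <- integer(nrow(combos))

  if (fast && method %in% c("adaptive_bin", "adaptive_smooth")) {
    arena <- cohort$trajectories[[1]]$arena
    fs <- 1 / arena$sample_rate
    ord <- order(smoothings)
    tally <- function(row, rate_vec, grid, agg, tf) {
      rep_ <- tryCatch({
        m <- mise_from_agg(rate_vec, agg)
        fe <- abs(detect_fields(matrix(rate_vec, grid$nx, grid$ny),
                                h = grid$h) - tf)
        c(m, fe, mean(is.na(rate_vec)))
      }, error = function(e) NULL)
      if (!is.null(rep_)) {
        acc[row, 1:3] <<- acc[row, 1:3] + rep_
        nok[row] <<- nok[row] + 1L
      }
    }
    for (b in bin_sizes) {
      grid <- map_grid(arena, b)
      radii <- adaptive_radii(b)
      aggs <- lapply(sessions, function(s) truth_bin_agg(s$cell$prob_map,
                                                         grid))
      for (tid in unique(vapply(sessions, function(s) as.integer(s$traj_id), 0L))) {
        traj <- cohort$trajectories[[tid]]
        pos <- bin_counts(traj$x, traj$y, grid)
        in_tr <- which(vapply(sessions, function(s) as.integer(s$traj_id), 0L) == tid)
        if (method == "adaptive_bin") {
          # radius per bin depends on the dwell map only: search once per
          # trajectory and reuse across its cells
          rs <- adaptive_bin_radius_cpp(pos, radii / b,
                                        smoothings[ord] / fs)
          for (si in in_tr) {
            s <- sessions[[si]]
            spk <- bin_counts(s$spikes$spike_x, s$spikes$spike_y, grid)
            for (k in seq_along(ord)) {
              ns <- disc_sum_at_idx_cpp(spk, rs$ridx[, k], radii / b)
              rate <- ns / (rs$np[, k] * fs)
              row <- which(combos$bin_size == b &
                             combos$smoothing == smoothings[ord[k]])
              tally(row, rate, grid, aggs[[si]], truth_fields[si])
            }
          }
        } else {
          for (si in in_tr) {
            s <- sessions[[si]]
            spk <- bin_counts(s$spikes$spike_x, s$spikes$spike_y, grid)
            res <- adaptive_expand_cpp(pos, spk, radii / b, smoothings[ord],
                                       fs, 2L)
            for (k in seq_along(ord)) {
              row <- which(combos$bin_size == b &
                             combos$smoothing == smoothings[ord[k]])
              tally(row, res$rates[, k], grid, aggs[[si]], truth_fields[si])
            }
          }
        }
      }
    }
    out <- cbind(combos,
                 base::sweep(acc[, 1:3, drop = FALSE], 1, pmax(nok, 1), "/"),
                 compute_time = NA_real_, n_cells = nok)
    out[nok == 0, c("mise", "field_detect_error", "empty_proportion")] <-
      NA_real_
  } else {
    for (row in seq_len(nrow(combos))) {
      b <- combos$bin_size[row]
      sm <- combos$smoothing[row]
      for (si in seq_along(sessions)) {
        s <- sessions[[si]]
        traj <- cohort$trajectories[[s$traj_id]]
        rep_ <- tryCatch({
          times <- numeric(max(1, time_reps))
          rm_ <- NULL
          for (k in seq_along(times)) {
            t0 <- proc.time()[["elapsed"]]
            rm_ <- build_rate_map(traj, s$spikes, method, b, sm)
            times[k] <- proc.time()[["elapsed"]] - t0
          }
          error_report(rm_, s$cell, compute_time = median(times),
                       truth_fields = truth_fields[si])
        }, error = function(e) NULL)
        if (!is.null(rep_)) {
          acc[row, ] <- acc[row, ] + c(rep_$mise, rep_$field_detect_error,
                                       rep_$empty_proportion,
                                       rep_$compute_time)
          nok[row] <- nok[row] + 1L
        }
      }
    }
    out <- cbind(combos, base::sweep(acc, 1, pmax(nok, 1), "/"),
                 n_cells = nok)
    out[nok == 0, c("mise", "field_detect_error", "empty_proportion",
                    "compute_time")] <- NA_real_
  }
  structure(out, method = method, class = c("sweep_result", "data.frame"))
}

#' Pareto front of a sweep
#'
#' Exhaustive non-dominated filtering of the evaluated grid points under the
#' minimized objectives (MISE, computation time, empty proportion, field
#' detection error).  A point is dominated if another evaluated point is no
#' worse on every objective and strictly better on at least one.
#'
#' @param sweep A `sweep_result`, or a plain data frame containing objective
#'   columns.
#' @param objectives Character vector of objective column names; columns
#'   that are entirely missing are dropped.
#' @return The non-dominated rows, with attribute `front_idx` giving their
#'   row indices in the input.
#' @export
pareto_front <- function(sweep,
                         objectives = c("mise", "compute_time",
                                        "empty_proportion",
                                        "field_detect_error")) {
  objectives <- intersect(objectives, names(sweep))
  keep <- vapply(objectives, function(o) !all(is.na(sweep[[o]])), logical(1))
  objectives <- objectives[keep]
  stopifnot(length(objectives) >= 1)
  M <- as.matrix(sweep[, objectives, drop = FALSE])
  ok <- stats::complete.cases(M)
  idx <- which(ok)
  Mo <- M[ok, , drop = FALSE]
  n <- nrow(Mo)
  nondom <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !nondom[i]) next
      if (all(Mo[j, ] <= Mo[i, ]) && any(Mo[j, ] < Mo[i, ])) {
        nondom[i] <- FALSE
        break
      }
    }
  }
  out <- sweep[idx[nondom], , drop = FALSE]
  attr(out, "front_idx") <- idx[nondom]
  attr(out, "objectives") <- objectives
  out
}

#' Balanced solution on a Pareto front
#'
#' Min-max normalizes MISE and computation time over the front and returns
#' the member closest (Euclidean distance) to the utopia point, the origin
#' of the normalized space (the per-objective front minima).  Ties are
#' broken toward smaller MISE.  When computation time is unavailable the
#' minimum-MISE member is returned.
#'
#' @param front Output of [pareto_front()].
#' @return A single row of `front`.
#' @export
select_balanced <- function(front) {
  stopifnot(nrow(front) >= 1)
  if (nrow(front) == 1) return(front)
  norm01 <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
  }
  m <- norm01(front$mise)
  if (!is.null(front$compute_time) && !all(is.na(front$compute_time))) {
    tt <- norm01(front$compute_time)
    d <- sqrt(m^2 + tt^2)
  } else d <- m
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[which.min(front$mise[best])]
  front[best, , drop = FALSE]
}

#' Minimum-error solution of a sweep
#'
#' @param sweep A `sweep_result`.
#' @return The row with the smallest mean MISE.
#' @export
select_min_error <- function(sweep) {
  sweep[which.min(sweep$mise), , drop = FALSE]
}

#' Regression of optimal parameters on field radius and duration
#'
#' Fits ordinary least-squares planes `binsize = b0 + b_r r + b_d d` and
#' `smoothing = b0 + b_r r + b_d d` to a design of selected solutions, where
#' `r` is the average field radius (mm) and `d` the recording duration
#' (minutes).
#'
#' @param solutions Data frame with columns `r`, `d`, `bin_size`,
#'   `smoothing`.
#' @return A `regression_fit`: list of coefficient vectors
#'   `(b0, b_r, b_d)` for `binsize` and `smoothing`.
#' @export
fit_parameter_regression <- function(solutions) {
  stopifnot(all(c("r", "d", "bin_size", "smoothing") %in% names(solutions)))
  fit1 <- function(y) {
    m <- lm(y ~ r + d, data = solutions)
    if (any(is.na(coef(m)))) stop("rank-deficient design")
    setNames(coef(m), c("b0", "b_r", "b_d"))
  }
  structure(list(binsize = fit1(solutions$bin_size),
                 smoothing = fit1(solutions$smoothing)),
            class = "regression_fit")
}

#' Published parameter-prescription coefficients
#'
#' Linear plug-in rules `b0 + b_r r + b_d d` (r = average field radius in
#' mm, d = session duration in minutes) for the bin size and smoothing of
#' each method, for both the minimum-error and balanced solutions.  Bin
#' sizes listed as "smallest available" are returned as the string
#' `"smallest"` and resolved by [predict_parameters()] from the caller's
#' minimum bin size.
#'
#' @return Nested list: `method -> solution type -> binsize / smoothing`.
#' @export
parameter_table_defaults <- function() {
  cf <- function(b0, br, bd) c(b0 = b0, b_r = br, b_d = bd)
  list(
    histogram = list(
      min_error = list(binsize = "smallest", smoothing = cf(16.232, 0.119, -0.218)),
      balanced = list(binsize = cf(22.229, 0.115, -0.413),
                      smoothing = cf(9.900, 0.278, -0.617))),
    ash = list(
      min_error = list(binsize = cf(76.339, 0.055, -0.278),
                       smoothing = cf(-29.982, 0.328, -0.085)),
      balanced = list(binsize = cf(56.510, 0.259, -0.513),
                      smoothing = cf(5.338, -0.006, -0.006))),
    adaptive_smooth = list(
      min_error = list(binsize = cf(1.7615, 0.0077, -0.0050),
                       smoothing = cf(-11872, 125, 281)),
      balanced = list(binsize = cf(9.714, 0.041, 0.104),
                      smoothing = cf(-9917, 61, 106))),
    adaptive_bin = list(
      min_error = list(binsize = cf(1.606, -0.004, 0.009),
                       smoothing = cf(-5.078, 0.041, 0.050)),
      balanced = list(binsize = cf(-5.451, 0.135, -0.055),
                      smoothing = cf(-4.336, 0.036, 0.045))),
    ksde = list(
      min_error = list(binsize = "smallest",
                       smoothing = cf(17.685, 0.133, -0.768)),
      balanced = list(binsize = cf(9.900, 0.099, -0.325),
                      smoothing = cf(14.806, 0.139, -0.707))),
    tksde = list(
      min_error = list(binsize = cf(3.529, 0.014, -0.020),
                       smoothing = cf(10.949, 0.213, -0.179)),
      balanced = list(binsize = cf(14.720, 0.104, -0.188),
                      smoothing = cf(19.304, 0.242, -0.222))))
}

#' Predict mapping parameters from field radius and duration
#'
#' Plug-in evaluation of the linear prescriptions, either from a fitted
#' [fit_parameter_regression()] object or from the shipped defaults of
#' [parameter_table_defaults()].
#'
#' @param method Method name.
#' @param solution_type `"balanced"` or `"min_error"`.
#' @param r Average field radius in mm (> 0).
#' @param d Recording duration in minutes (> 0).
#' @param fit Optional `regression_fit` overriding the defaults.
#' @param min_bin Bin size (mm) substituted where the prescription is
#'   "smallest available".
#' @return A list with `bin_size` and `smoothing`.
#' @examples
#' predict_parameters("histogram", "balanced", r = 179, d = 16,
#'                    min_bin = 2.5)
#' @export
predict_parameters <- function(method, solution_type = c("balanced",
                                                         "min_error"),
                               r, d, fit = NULL, min_bin = 2.5) {
  solution_type <- match.arg(solution_type)
  if (!is.finite(r) || r < 0 || !is.finite(d) || d < 0)
    stop("r and d must be non-negative")
  if (is.null(fit)) {
    tab <- parameter_table_defaults()
    method <- match.arg(method, names(tab))
    fit <- tab[[method]][[solution_type]]
  }
  ev <- function(cfv) {
    if (is.character(cfv)) return(min_bin)
    unname(cfv["b0"] + cfv["b_r"] * r + cfv["b_d"] * d)
  }
  list(bin_size = ev(fit$binsize), smoothing = ev(fit$smoothing))
}
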