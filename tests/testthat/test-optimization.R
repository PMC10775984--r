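test_that("the Pareto front matches an O(n^2) dominance oracle", {
  set.seed(13)
  df <- data.frame(bin_size = 1:50, smoothing = 1,
                   mise = runif(50), compute_time = runif(50),
                   empty_proportion = runif(50),
                   field_detect_error = sample(0:3, 50, TRUE))
  fr <- pareto_front(df)
  M <- as.matrix(df[, c("mise", "compute_time", "empty_proportion",
                        "field_detect_error")])
  dominated <- sapply(seq_len(50), function(i)
    any(sapply(seq_len(50), function(j)
      j != i && all(M[j, ] <= M[i, ]) && any(M[j, ] < M[i, ]))))
  expect_setequal(attr(fr, "front_idx"), which(!dominated))
  # every front member is undominated against the full grid
  for (i in attr(fr, "front_idx")) expect_false(dominated[i])
})

test_that("degenerate fronts behave", {
  one <- data.frame(bin_size = 1, smoothing = 1, mise = 0.5,
                    compute_time = 1, empty_proportion = 0,
                    field_detect_error = 0)
  expect_equal(nrow(pareto_front(one)), 1)
  two <- rbind(one, within(one, { mise <- 1; compute_time <- 2 }))
  fr <- pareto_front(two)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$mise, 0.5)
})

test_that("the balanced solution minimizes normalized distance to utopia", {
  fr <- data.frame(bin_size = 1:3, smoothing = 1,
                   mise = c(0.1, 0.5, 0.9),
                   compute_time = c(0.9, 0.5, 0.1))
  bal <- select_balanced(fr)
  expect_equal(bal$bin_size, 2)   # (0.5, 0.5) is closest to (0, 0)
  # a member achieving both minima is selected with distance zero
  fr2 <- rbind(fr, data.frame(bin_size = 4, smoothing = 1, mise = 0.1,
                              compute_time = 0.1))
  expect_equal(select_balanced(fr2)$bin_size, 4)
  expect_equal(select_balanced(fr[1, ])$bin_size, 1)
})

test_that("parameter regression recovers noiseless planes", {
  design <- expand.grid(r = c(126, 179, 253), d = c(4, 16, 64))
  design$bin_size <- 10 + 0.2 * design$r - 0.5 * design$d
  design$smoothing <- -3 + 0.05 * design$r + 0.1 * design$d
  fit <- fit_parameter_regression(design)
  expect_equal(unname(fit$binsize), c(10, 0.2, -0.5), tolerance = 1e-9)
  expect_equal(unname(fit$smoothing), c(-3, 0.05, 0.1), tolerance = 1e-9)
  # hand-computed normal equations on the 9-point design
  X <- cbind(1, design$r, design$d)
  beta <- solve(t(X) %*% X, t(X) %*% design$bin_size)
  expect_equal(unname(fit$binsize), as.numeric(beta), tolerance = 1e-9)
  bad <- design
  bad$d <- bad$r   # collinear
  expect_error(fit_parameter_regression(bad), "rank")
})

test_that("plug-in prescriptions evaluate the published coefficients", {
  p <- predict_parameters("histogram", "balanced", r = 179, d = 16)
  expect_equal(p$bin_size, 22.229 + 0.115 * 179 - 0.413 * 16,
               tolerance = 1e-12)
  expect_equal(p$bin_size, 36.2, tolerance = 0.05)
  expect_equal(p$smoothing, 9.900 + 0.278 * 179 - 0.617 * 16,
               tolerance = 1e-12)
  # "smallest available" bin sizes resolve to the caller's minimum
  expect_equal(predict_parameters("ksde", "min_error", 179, 16,
                                  min_bin = 2.5)$bin_size, 2.5)
  expect_equal(predict_parameters("histogram", "min_error", 179, 16,
                                  min_bin = 5)$bin_size, 5)
  # zero inputs return the intercepts
  p0 <- predict_parameters("tksde", "balanced", r = 0, d = 0)
  expect_equal(p0$bin_size, 14.720)
  expect_equal(p0$smoothing, 19.304)
  expect_error(predict_parameters("histogram", "balanced", r = -1, d = 16),
               "non-negative")
})

test_that("a 1x1 sweep produces a single averaged report", {
  cohort <- list(trajectories = list(fix$traj),
                 sessions = list(list(cell = fix$cell, traj_id = 1,
                                      spikes = fix$spikes)))
  sw <- sweep_method("histogram", cohort, 50, 50, time_reps = 1)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$n_cells, 1)
  expect_equal(sw$mise, mise(histogram_map(fix$traj, fix$spikes, 50, 50),
                             fix$cell), tolerance = 1e-12)
  # the stacked adaptive path equals per-combination construction
  sw2 <- sweep_method("adaptive_bin", cohort, c(50, 100), c(0.5, 2),
                      fast = TRUE)
  for (i in seq_len(nrow(sw2))) {
    rm_ <- adaptive_bin_map(fix$traj, fix$spikes, sw2$bin_size[i],
                            sw2$smoothing[i])
    expect_equal(sw2$mise[i], mise(rm_, fix$cell), tolerance = 1e-10)
    expect_equal(sw2$empty_proportion[i], empty_proportion(rm_))
  }
})
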