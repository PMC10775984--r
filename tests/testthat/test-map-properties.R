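# Shared property checks across all six estimators.

methods_grid <- list(
  histogram = list(bin_size = 60, smoothing = 60),
  ash = list(bin_size = 60, smoothing = 4),
  adaptive_smooth = list(bin_size = 60, smoothing = 3200),
  adaptive_bin = list(bin_size = 60, smoothing = 1),
  ksde = list(bin_size = 60, smoothing = 50),
  tksde = list(bin_size = 60, smoothing = 50))

test_that("every method recovers the rate of a uniform cell", {
  set.seed(18)
  n <- 30000
  tr <- toy_traj(runif(n, 0, 1200), runif(n, 0, 1200))
  p <- 0.04   # 2 Hz at 50 Hz sampling
  sp <- suppressWarnings(simulate_spikes(const_cell(p), tr, seed = 19,
                                         background_lambda = 0))
  true_rate <- sp$n_spikes / (n * 0.02)
  se <- sqrt(sp$n_spikes) / (n * 0.02)
  for (m in names(methods_grid)) {
    rm_ <- build_rate_map(tr, sp, m, methods_grid[[m]]$bin_size,
                          methods_grid[[m]]$smoothing)
    got <- mean(rm_$rate, na.rm = TRUE)
    expect_lt(abs(got - true_rate), 3 * se + 0.05 * true_rate,
              label = sprintf("%s visited-bin mean (%.3f vs %.3f)",
                              m, got, true_rate))
  }
})

test_that("rates are finite and non-negative wherever not missing", {
  for (m in names(methods_grid)) {
    rm_ <- build_rate_map(fix$traj, fix$spikes, m,
                          methods_grid[[m]]$bin_size,
                          methods_grid[[m]]$smoothing)
    v <- rm_$rate[!is.na(rm_$rate)]
    expect_true(all(is.finite(v) & v >= 0), label = m)
  }
})

test_that("map construction is deterministic", {
  for (m in c("histogram", "adaptive_bin", "ksde")) {
    r1 <- build_rate_map(fix$traj, fix$spikes, m,
                         methods_grid[[m]]$bin_size,
                         methods_grid[[m]]$smoothing)
    r2 <- build_rate_map(fix$traj, fix$spikes, m,
                         methods_grid[[m]]$bin_size,
                         methods_grid[[m]]$smoothing)
    expect_identical(r1$rate, r2$rate, label = m)
  }
})

test_that("longer recordings give more accurate maps on average", {
  cells <- lapply(1:3, function(i)
    simulate_place_cell(fix$arena, "medium", seed = 500 + i))
  tr16 <- simulate_random_walk(fix$arena, random_walk_config(), 960,
                               seed = 600)
  tr4 <- clip_trajectory(tr16, 240)
  worse <- sapply(seq_along(cells), function(i) {
    sp16 <- suppressWarnings(simulate_spikes(cells[[i]], tr16,
                                             seed = 700 + i))
    sp4 <- suppressWarnings(simulate_spikes(cells[[i]], tr4,
                                            seed = 700 + i))
    c(mise(histogram_map(tr4, sp4, 40, 60), cells[[i]]),
      mise(histogram_map(tr16, sp16, 40, 60), cells[[i]]))
  })
  expect_lt(mean(worse[2, ]), mean(worse[1, ]))
})
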