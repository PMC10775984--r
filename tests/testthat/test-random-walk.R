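test_that("trajectory length, spacing and bounds follow the sampling spec", {
  a <- arena_spec()
  tr <- simulate_random_walk(a, random_walk_config(), duration = 10, seed = 1)
  expect_length(tr$t, 10 * 50)
  expect_equal(unique(round(diff(tr$t), 10)), 0.02)
  expect_true(all(tr$x >= 0 & tr$x <= a$width))
  expect_true(all(tr$y >= 0 & tr$y <= a$height))
  tr1 <- simulate_random_walk(a, random_walk_config(upsample_factor = 50),
                              duration = 1, seed = 2)
  expect_length(tr1$x, 50)
})

test_that("invalid walk inputs are rejected", {
  a <- arena_spec()
  expect_error(simulate_random_walk(a, random_walk_config(), duration = 0.5),
               "decision step")
  expect_error(random_walk_config(step_sigma = NaN), "non-finite")
})

test_that("clipping returns an exact, idempotent prefix", {
  a <- arena_spec()
  tr <- simulate_random_walk(a, random_walk_config(), 120, seed = 3)
  cl <- clip_trajectory(tr, 60)
  expect_length(cl$t, 60 * 50)
  expect_identical(cl$x, tr$x[1:3000])
  expect_identical(cl$t, tr$t[1:3000])
  expect_identical(clip_trajectory(cl, 60), cl)
  expect_identical(clip_trajectory(tr, 120)$x, tr$x)
  expect_error(clip_trajectory(cl, 120), "longer")
})

test_that("identical seeds give bitwise-identical walks", {
  a <- arena_spec()
  t1 <- simulate_random_walk(a, random_walk_config(), 30, seed = 7)
  t2 <- simulate_random_walk(a, random_walk_config(), 30, seed = 7)
  t3 <- simulate_random_walk(a, random_walk_config(), 30, seed = 8)
  expect_identical(t1, t2)
  expect_false(identical(t1$x, t3$x))
})

test_that("walks cover the arena interior close to uniformly", {
  a <- arena_spec()
  g <- map_grid(a, 100)
  cvs <- sapply(21:23, function(s) {
    tr <- simulate_random_walk(a, random_walk_config(), 960, seed = s)
    d <- bin_data(tr, NULL, g)$dwell
    inter <- d[2:(g$nx - 1), 2:(g$ny - 1)]
    sd(inter) / mean(inter)
  })
  expect_true(all(cvs < 1.0))
})

test_that("goal and thigmotaxis biases shift the dwell distribution", {
  a <- arena_spec()
  un <- simulate_random_walk(a, random_walk_config(), 240, seed = 31)
  gl <- simulate_random_walk(a, random_walk_config(bias_mode = "goal"),
                             240, seed = 31)
  th <- simulate_random_walk(a, random_walk_config(bias_mode = "thigmotaxis"),
                             240, seed = 31)
  dgoal <- function(t) mean(sqrt((t$x - 900)^2 + (t$y - 600)^2))
  dwall <- function(t) mean(pmin(t$x, a$width - t$x, t$y, a$height - t$y))
  expect_lt(dgoal(gl), dgoal(un))
  expect_lt(dwall(th), dwall(un))
})
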