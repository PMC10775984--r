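test_that("a dense single cluster satisfies the criterion at the first radius", {
  # 1000 samples and 100 spikes at one point, alpha = 1000: the required
  # radius is 1000 / (1000 * sqrt(100)) = 0.1 bin widths, met immediately
  tr <- toy_traj(rep(625, 1000), rep(625, 1000))
  sp <- toy_spikes(rep(625, 100), rep(625, 100), t = rep(0, 100),
                   duration = 20)
  rm_ <- adaptive_smooth_map(tr, sp, 50, alpha = 1000)
  expect_equal(rm_$params$radius_idx[13, 13], 1)
  expect_equal(rm_$rate[13, 13], 100 / (1000 * 0.02))
})

test_that("pixelwise and convolution adaptive smoothing agree closely", {
  conv <- adaptive_smooth_map(fix16$traj, fix16$spikes, 50, alpha = 3200)
  pix <- adaptive_smooth_map(fix16$traj, fix16$spikes, 50, alpha = 3200,
                             impl = "pixelwise")
  both <- !is.na(conv$rate) & !is.na(pix$rate)
  expect_gt(mean(both), 0.9)
  expect_gt(cor(conv$rate[both], pix$rate[both]), 0.99)
})

test_that("pixelwise and convolution adaptive binning agree closely", {
  conv <- adaptive_bin_map(fix16$traj, fix16$spikes, 50, t = 1)
  pix <- adaptive_bin_map(fix16$traj, fix16$spikes, 50, t = 1,
                          impl = "pixelwise")
  both <- !is.na(conv$rate) & !is.na(pix$rate)
  expect_gt(mean(both), 0.9)
  expect_gt(cor(conv$rate[both], pix$rate[both]), 0.99)
})

test_that("the densest bin keeps its raw ratio when t is already enclosed", {
  b <- bin_data(fix$traj, fix$spikes, map_grid(fix$arena, 100))
  k <- which(b$dwell == max(b$dwell), arr.ind = TRUE)[1, ]
  rm_ <- adaptive_bin_map(fix$traj, fix$spikes, 100,
                          t = max(b$dwell) * 0.99)
  expect_equal(rm_$params$radius_idx[k[1], k[2]], 1)
  expect_equal(rm_$rate[k[1], k[2]],
               (b$spike_counts / b$dwell)[k[1], k[2]])
})

test_that("uniform dwell expands the radius to enclose the required time", {
  # 5 samples (0.1 s) per 50 mm bin; t = 1 s needs at least 10 bins
  g <- map_grid(arena_spec(), 50)
  cx <- ratemapr:::grid_centers_x(g)
  cy <- ratemapr:::grid_centers_y(g)
  pts <- expand.grid(x = cx, y = cy)
  tr <- toy_traj(rep(pts$x, 5), rep(pts$y, 5))
  sp <- toy_spikes(600, 600, 0, duration = length(tr$t) * 0.02)
  rm_ <- adaptive_bin_map(tr, sp, 50, t = 1)
  k <- rm_$params$radius_idx[12, 12]   # interior bin
  expect_gt(k, 1)
  enclosed <- sum((sqrt(outer((seq_len(g$nx) - 12)^2,
                              (seq_len(g$ny) - 12)^2, "+")) <=
                     rm_$params$radii[k] / 50))
  expect_gte(enclosed * 0.1, 1)
  if (k > 1) {
    prev <- sum((sqrt(outer((seq_len(g$nx) - 12)^2,
                            (seq_len(g$ny) - 12)^2, "+")) <=
                   rm_$params$radii[k - 1] / 50))
    expect_lt(prev * 0.1, 1)
  }
})

test_that("unsatisfiable criteria leave bins missing, with a warning for t", {
  tr <- toy_traj(rep(625, 10), rep(625, 10))
  expect_warning(rm_ <- adaptive_bin_map(tr, toy_spikes(625, 625, 0, 0.2),
                                         50, t = 10),
                 "shorter")
  expect_true(all(is.na(rm_$rate)))
  # no spikes anywhere: adaptive smoothing cannot satisfy its criterion
  sp0 <- toy_spikes(numeric(0), numeric(0), t = numeric(0), duration = 0.2)
  rm2 <- adaptive_smooth_map(fix$traj, sp0, 100, alpha = 3200)
  expect_true(all(is.na(rm2$rate)))
})
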