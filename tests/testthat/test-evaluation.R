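small_arena <- arena_spec(width = 6, height = 6, grid_resolution = 1)

test_that("MISE is zero for proportional maps and matches a hand oracle", {
  f <- matrix(runif(36), 6, 6)
  g <- map_grid(small_arena, 2)
  r <- matrix(runif(9), 3, 3)
  rm_ <- ratemapr:::new_rate_map(r, g, "toy")
  # brute-force Riemann oracle over the 1 mm lattice
  r1 <- matrix(NA_real_, 6, 6)
  for (i in 1:6) for (j in 1:6) r1[i, j] <- r[ceiling(i / 2), ceiling(j / 2)]
  rn <- r1 / sum(r1); fn <- f / sum(f)
  acc <- 0
  for (i in 1:6) for (j in 1:6) acc <- acc + (rn[i, j] - fn[i, j])^2
  expect_equal(mise(rm_, f), acc / 36, tolerance = 1e-12)
  # proportionality and rate-map rescaling leave MISE unchanged / at zero
  prop <- ratemapr:::new_rate_map(3 * f[seq(1, 6, 1), ], map_grid(small_arena, 1), "toy")
  expect_equal(mise(prop, f), 0, tolerance = 1e-15)
  rm2 <- rm_; rm2$rate <- rm_$rate * 7
  expect_equal(mise(rm2, f), mise(rm_, f), tolerance = 1e-15)
})

test_that("missing bins are excluded from the MISE support", {
  f <- matrix(1, 6, 6)
  g <- map_grid(small_arena, 2)
  r <- matrix(c(NA, 1, 1, 1, NA, 1, 1, 1, NA), 3, 3)
  rm_ <- ratemapr:::new_rate_map(r, g, "toy")
  expect_equal(mise(rm_, f), 0, tolerance = 1e-15)   # uniform on support
  rall <- ratemapr:::new_rate_map(matrix(NA_real_, 3, 3), g, "toy")
  expect_error(mise(rall, f), "missing")
})

test_that("the aggregated sweep MISE equals the reference implementation", {
  cell <- fix$cell
  rm_ <- histogram_map(fix$traj, fix$spikes, 70, sigma = 70)
  agg <- ratemapr:::truth_bin_agg(cell$prob_map, rm_$grid)
  expect_equal(ratemapr:::mise_from_agg(as.vector(rm_$rate), agg),
               mise(rm_, cell), tolerance = 1e-12)
})

test_that("field detection thresholds, areas and connectivity behave", {
  m <- matrix(0, 40, 40)
  m[5:14, 5:14] <- 1           # 10x10 bins of 10 mm = 10000 mm^2
  expect_equal(detect_fields(m, h = 10), 1)
  expect_equal(detect_fields(matrix(0, 10, 10), h = 10), 0)
  # two bumps of 2500 mm^2 are below the 3600 mm^2 cutoff
  m2 <- matrix(0, 40, 40)
  m2[2:6, 2:6] <- 1
  m2[30:34, 30:34] <- 1
  expect_equal(detect_fields(m2, h = 10), 0)
  # rescaling the map does not change the count
  expect_equal(detect_fields(m * 100, h = 10), detect_fields(m, h = 10))
  # diagonal touch merges under 8- but not 4-connectivity
  m3 <- matrix(0, 40, 40)
  m3[2:8, 2:8] <- 1
  m3[9:15, 9:15] <- 1
  expect_equal(detect_fields(m3, h = 10, conn = 8), 1)
  expect_equal(detect_fields(m3, h = 10, conn = 4), 2)
})

test_that("component labelling matches a BFS oracle", {
  set.seed(12)
  mask <- matrix(runif(400) < 0.4, 20, 20)
  bfs_count <- function(mask, conn) {
    seen <- matrix(FALSE, nrow(mask), ncol(mask))
    nb <- if (conn == 8) cbind(c(1,-1,0,0,1,1,-1,-1), c(0,0,1,-1,1,-1,1,-1))
          else cbind(c(1,-1,0,0), c(0,0,1,-1))
    count <- 0
    for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
      if (!mask[i, j] || seen[i, j]) next
      count <- count + 1
      queue <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nb))) {
          ii <- p[1] + nb[k, 1]; jj <- p[2] + nb[k, 2]
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj] && !seen[ii, jj]) {
            seen[ii, jj] <- TRUE
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
    }
    count
  }
  for (conn in c(4L, 8L)) {
    lab <- ratemapr:::label_components_cpp(mask, conn)
    expect_equal(max(lab), bfs_count(mask, conn))
    expect_identical(lab > 0, unname(mask))
  }
})

test_that("field detection error and empty proportion are simple arithmetic", {
  expect_equal(field_detect_error(
    histogram_map(fix$traj, fix$spikes, 50, 50), fix$cell,
    truth_fields = detect_fields(fix$cell$prob_map, h = 1)),
    field_detect_error(histogram_map(fix$traj, fix$spikes, 50, 50),
                       fix$cell))
  g <- map_grid(small_arena, 2)
  r <- matrix(c(NA, 1, NA, 1, NA, 1, NA, 1, NA), 3, 3)
  rm_ <- ratemapr:::new_rate_map(r, g, "toy")
  expect_equal(empty_proportion(rm_), 5 / 9)
  full <- ratemapr:::new_rate_map(matrix(1, 3, 3), g, "toy")
  expect_equal(empty_proportion(full), 0)
  # sparse unsmoothed 4-minute histogram at 5 mm bins is mostly empty
  sparse <- histogram_map(fix$traj, fix$spikes, 5, sigma = 0)
  expect_gt(empty_proportion(sparse), 0.5)
})

test_that("alternative metrics hit their analytic extremes", {
  f <- matrix(runif(36) + 0.1, 6, 6)
  ident <- ratemapr:::new_rate_map(2 * f, map_grid(small_arena, 1), "toy")
  am <- alt_metrics(ident, f)
  expect_equal(am$pearson_r, 1, tolerance = 1e-12)
  expect_equal(am$euclidean, 0, tolerance = 1e-12)
  anti <- ratemapr:::new_rate_map(max(f) + min(f) - f,
                                  map_grid(small_arena, 1), "toy")
  expect_equal(alt_metrics(anti, f)$pearson_r, -1, tolerance = 1e-12)
})
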