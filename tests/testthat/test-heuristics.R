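test_that("Ripley functions satisfy their defining identities and oracle", {
  set.seed(14)
  x <- runif(300, 0, 1200); y <- runif(300, 0, 1200)
  radii <- seq(10, 400, length.out = 20)
  rc <- ripley_h(x, y, radii, area = 1200^2)
  expect_equal(rc$L, sqrt(rc$K / pi), tolerance = 1e-12)
  expect_equal(rc$H, rc$L - rc$r, tolerance = 1e-12)
  # O(n^2) pair-count oracle
  lambda <- 300 / 1200^2
  Kref <- sapply(radii, function(r) {
    cnt <- 0
    for (i in 1:300) cnt <- cnt +
        sum(sqrt((x - x[i])^2 + (y - y[i])^2) <= r) - 1
    cnt / 300 / lambda
  })
  expect_equal(rc$K, Kref, tolerance = 1e-12)
})

test_that("three collinear points give the hand-counted K", {
  x <- c(0, 100, 200); y <- c(0, 0, 0)
  rc <- ripley_h(x, y, c(50, 100, 150, 250), area = 1200^2)
  lambda <- 3 / 1200^2
  # pairs within r: r=50: 0; r=100: 4 ordered; r=150: 4; r=250: 6
  expect_equal(rc$K, c(0, 4, 4, 6) / 3 / lambda)
  expect_error(ripley_h(1, 1, 10, area = 100), "two points")
})

test_that("complete spatial randomness keeps H near zero, clusters peak", {
  set.seed(15)
  x <- runif(3000, 0, 1200); y <- runif(3000, 0, 1200)
  radii <- seq(10, 300, length.out = 30)
  rc <- ripley_h(x, y, radii, area = 1200^2)
  # no edge correction: H is unbiased only well below the arena scale
  expect_lt(max(abs(rc$H[rc$r <= 100])), 15)
  # clustered pattern: H has a positive interior maximum
  cx <- rnorm(1500, 600, 60); cy <- rnorm(1500, 600, 60)
  rcc <- ripley_h(cx, cy, radii, area = 1200^2)
  pk <- which.max(rcc$H)
  expect_gt(rcc$H[pk], 50)
  expect_gt(pk, 1); expect_lt(pk, length(radii))
})

test_that("field-radius estimation is scale-equivariant and calibrated", {
  set.seed(16)
  rho <- 100   # 2 SD radius of an isotropic Gaussian cluster, sigma = 50
  sx <- rnorm(800, 600, rho / 2); sy <- rnorm(800, 600, rho / 2)
  est <- estimate_field_radius(list(spike_x = sx, spike_y = sy),
                               arena_spec())
  expect_gt(est, 0.5 * rho)
  expect_lt(est, 1.5 * rho)
  big <- arena_spec(width = 2400, height = 2400)
  est2 <- estimate_field_radius(list(spike_x = 2 * sx, spike_y = 2 * sy),
                                big)
  expect_equal(est2, 2 * est, tolerance = 0.1)
  expect_error(estimate_field_radius(list(spike_x = c(1, 1),
                                          spike_y = c(1, 1)),
                                     arena_spec()), "degenerate")
})

test_that("Sturges' rule reproduces the published bin sizes", {
  a <- arena_spec()
  expect_equal(sturges_bins(16 * 60 * 50, a), 70)
  expect_equal(sturges_bins(64 * 60 * 50, a), 63)
  expect_equal(sturges_bins(1, a), 1200)
  # monotone non-increasing in N
  sizes <- sapply(10^(1:6), sturges_bins, arena = a)
  expect_true(all(diff(sizes) <= 0))
  expect_error(sturges_bins(0, a), "sample")
})

test_that("Freedman-Diaconis widths follow the closed form and scale", {
  set.seed(17)
  n <- 48000
  x <- runif(n, 0, 1200); y <- runif(n, 0, 1200)
  # uniform IQR is 600, so the width is 2 * 600 * n^(-1/3) ~ 33 mm
  expect_equal(fd_bins(x, y), 2 * 600 * n^(-1 / 3), tolerance = 0.05)
  expect_equal(fd_bins(3 * x, 3 * y), 3 * fd_bins(x, y))
  expect_equal(fd_bins(x, y, "l2_norm"),
               2 * IQR(sqrt(x^2 + y^2)) * n^(-1 / 3))
  expect_error(fd_bins(rep(1, 10), rep(1, 10)), "interquartile")
})
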