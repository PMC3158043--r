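test_that("window size follows the size/disparity relation", {
  quad <- size_disparity_relation("quadratic")
  expect_equal(window_sigma(quad, 0), 3)
  expect_equal(window_sigma(quad, 13), 8.408)
  expect_equal(window_sigma(quad, 7.6), 4.84832)        # 2 sigma ~ 10 arcmin
  expect_equal(window_sigma(quad, -13), window_sigma(quad, 13))  # even
  cst <- size_disparity_relation("constant")
  expect_equal(window_sigma(cst, c(-9, 0, 12.3)), rep(3, 3))
  lin <- size_disparity_relation("linear", lin_slope = 0.24)
  expect_equal(window_sigma(lin, -10), 3 + 2.4)
  # non-decreasing in |dx| for all kinds
  dxs <- seq(0, 13, by = 0.6)
  for (r in list(quad, cst, lin))
    expect_true(all(diff(window_sigma(r, dxs)) >= 0))
})

test_that("windowed correlation hits its exact anchor cases", {
  set.seed(3)
  n <- 41
  L <- matrix(rnorm(n * n), n, n)
  pair_same <- stereo_pair(L, L, 0.6)
  expect_equal(windowed_correlation(pair_same, 21, 21, 0, 3), 1)
  pair_anti <- stereo_pair(L, -L, 0.6)
  expect_equal(windowed_correlation(pair_anti, 21, 21, 0, 3), -1)
  # matching content at a nonzero offset
  R <- cbind(L[, 6:n], matrix(rnorm(n * 5), n, 5))
  pair_off <- stereo_pair(L, R, 0.6)
  expect_equal(windowed_correlation(pair_off, 21, 21, -3, 3), 1)
  # blank window is flagged undefined, never +/- 1
  pair_blank <- stereo_pair(matrix(0, n, n), L, 0.6)
  expect_true(is.na(windowed_correlation(pair_blank, 21, 21, 0, 3)))
  # window that does not fit is an error
  expect_error(windowed_correlation(pair_same, 3, 21, 0, 3), "fit")
})

test_that("windowed correlation equals a hand-built weighted Pearson", {
  # 3 x 3 patches, sigma spanning the patch: replicate the definition with
  # plain arithmetic (weights, then the Pearson formula written out)
  L <- matrix(c(1, -2, 0.5, 3, 0, -1, 2, 1, -0.5), 3, 3)
  R <- matrix(c(0.5, -1, 1, 2.5, 0.2, -2, 1, 0, 0.3), 3, 3)
  pair <- stereo_pair(L, R, 1)
  sigma <- 0.9                      # 2 sigma = 1.8 px: half-width 1 px
  g <- exp(-(-1:1)^2 / (2 * 0.9^2))
  w <- outer(g, g)
  a <- as.numeric(w * L); b <- as.numeric(w * R)
  n <- 9
  r_hand <- (sum(a * b) - sum(a) * sum(b) / n) /
    sqrt((sum(a^2) - sum(a)^2 / n) * (sum(b^2) - sum(b)^2 / n))
  expect_equal(windowed_correlation(pair, 2, 2, 0, sigma), r_hand)
})

test_that("the surface agrees with the direct single-point oracle", {
  prof <- disparity_profile("sine", 1.3, 5.1)
  pair <- simulate_stimulus(prof, tiny_config(), seed = 9)
  grid <- correlator_grid()
  rel <- size_disparity_relation("quadratic")
  surf <- correlation_surface(pair, grid, rel)
  set.seed(21)
  dev <- 0
  for (i in 1:100) {
    di <- sample(length(grid$disparities), 1)
    dx <- grid$disparities[di]
    sig <- window_sigma(rel, dx)
    m <- stereocorr:::trunc_halfwidth_px(sig, 0.6)
    yy <- sample((m + 1):(nrow(pair$left) - m), 1)
    w <- windowed_correlation(pair, surf$x_col, yy, dx, sig)
    dev <- max(dev, abs(w - surf$C[yy, di]))
  }
  expect_lt(dev, 1e-10)
})

test_that("surface values are bounded, edge-flagged, and scale invariant", {
  prof <- disparity_profile("square", 1.3, 2.5)
  pair <- simulate_stimulus(prof, tiny_config(), seed = 13)
  grid <- correlator_grid()
  rel <- size_disparity_relation("quadratic")
  surf <- correlation_surface(pair, grid, rel)
  expect_true(all(abs(surf$C) <= 1, na.rm = TRUE))
  # rows where the largest window does not fit are NA
  dmax <- max(grid$disparities)
  mmax <- stereocorr:::trunc_halfwidth_px(window_sigma(rel, dmax), 0.6)
  expect_true(all(is.na(surf$C[1:mmax, ncol(surf$C)])))
  expect_false(anyNA(surf$C[(mmax + 1):(nrow(surf$C) - mmax), ncol(surf$C)]))
  # multiplying both images by positive constants leaves C unchanged
  pair2 <- stereo_pair(17 * pair$left, 0.3 * pair$right, 0.6)
  surf2 <- correlation_surface(pair2, grid, rel)
  expect_equal(surf2$C, surf$C, tolerance = 1e-12)
  # eye swap + disparity negation is a symmetry once the window pair is
  # re-anchored on the (former) right-eye column
  swap <- stereo_pair(pair$right, pair$left, 0.6)
  for (dx in c(-4.8, 0, 3.6, 9.6)) {
    sig <- window_sigma(rel, dx)
    s_px <- as.integer(round(dx / 0.6))
    expect_equal(
      windowed_correlation(swap, surf$x_col + s_px, 60, -dx, sig),
      windowed_correlation(pair, surf$x_col, 60, dx, sig))
  }
})

test_that("the population ridge tracks uniform stimulus disparity", {
  # constant-disparity stimulus: argmax over dx of the mean response equals
  # the stimulus disparity (20 seeds)
  grid <- correlator_grid()
  rel <- size_disparity_relation("quadratic")
  cfg <- tiny_config()
  set.seed(77)
  hits <- vapply(1:20, function(s) {
    d0 <- sample(seq(-6, 6, by = 1.2), 1)
    prof <- disparity_profile("square", 0.01, abs(d0),
                              phase = if (d0 >= 0) 90 else 270)
    surf <- encode_stimulus(prof, cfg, seed = s)
    mc <- colMeans(surf$C, na.rm = TRUE)
    abs(grid$disparities[which.max(mc)] - d0) < 1e-9
  }, logical(1))
  expect_true(all(hits))
  # binocularly uncorrelated control (independent dot fields per eye):
  # mean response ~ 0
  p0 <- disparity_profile("sine", 3.8, 0)
  a <- simulate_stimulus(p0, cfg, seed = 51)
  b <- simulate_stimulus(p0, cfg, seed = 52)
  unc <- stereo_pair(a$left, b$right, 0.6)
  surf <- correlation_surface(unc, grid, rel)
  vals <- surf$C[!is.na(surf$C)]
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("within-window disparity ranges match the closed forms", {
  peak <- disparity_profile("sine", 3.8, 1.3, phase = 90)
  cross <- disparity_profile("sine", 3.8, 1.3, phase = 0)
  h <- 3
  closed_peak <- 1.3 * (1 - cos(2 * pi * 3.8 * h / 60))
  closed_cross <- 2 * 1.3 * sin(2 * pi * 3.8 * h / 60)
  expect_equal(disparity_range_in_window(peak, 0, h), closed_peak)
  expect_equal(disparity_range_in_window(cross, 0, h), closed_cross)
  expect_equal(disparity_range_in_window(peak, 0, 0), 0)
  # square wave: window straddling one edge sees the full 2A range
  sq <- disparity_profile("square", 3.8, 5, phase = 0)
  expect_equal(disparity_range_in_window(sq, 0, 3), 10)
  # window inside one half-cycle sees zero range
  quarter <- 1 / (4 * 3.8)
  expect_equal(disparity_range_in_window(sq, quarter, 1), 0)
  # noise profiles are rejected
  pn <- disparity_profile("noise", amplitude = 2, noise_parent = "sine")
  expect_error(disparity_range_in_window(pn, 0, 3))
})
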