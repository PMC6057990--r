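test_that("artifact detector flags sentinel valleys and their neighborhoods", {
  # clean surface: nothing flagged
  spec <- texture_spec("toy", 40, grid_shape = c(60, 60), pixel_pitch = 4)
  surf <- generate_surface(spec, 3)
  expect_equal(sum(detect_artifacts(surf)), 0)

  # single sentinel in a flat grid: the pixel plus its 8 neighbors
  g <- matrix(5, 7, 7)
  g[4, 4] <- -1000
  m <- detect_artifacts(g, pitch = 1)
  expect_equal(sum(m), 9)
  expect_true(all(m[3:5, 3:5]))

  # injected valley sentinels: high recall, clean core detections
  inj <- inject_profilometry_errors(surf, 0.02, seed = 2)
  truth <- attr(inj, "truth_mask")
  mk <- detect_artifacts(inj)
  core <- attr(mk, "core")
  expect_gte(sum(mk & truth) / sum(truth), 0.95)
  expect_gte(sum(core & truth) / sum(core), 0.9)

  expect_error(detect_artifacts(matrix(1, 2, 2), pitch = 1), "3")
})

test_that("linear interpolation restores flats and ramps exactly", {
  flat <- matrix(7, 9, 9)
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  out <- interpolate_artifacts(flat, m, pitch = 1)
  expect_equal(out$heights[5, 5], 7)

  ramp <- outer(1:10, 1:10, function(i, j) 3 * i + 2 * j)
  m2 <- matrix(FALSE, 10, 10); m2[4, 3:6] <- TRUE; m2[7, 5] <- TRUE
  out2 <- interpolate_artifacts(ramp, m2, pitch = 1)
  expect_equal(out2$heights, ramp)

  # empty mask: identity
  out3 <- interpolate_artifacts(ramp, matrix(FALSE, 10, 10), pitch = 1)
  expect_identical(out3$heights, ramp)
})

test_that("cleaning never inflates the height variance", {
  spec <- texture_spec("toy", 40, grid_shape = c(60, 60), pixel_pitch = 4)
  surf <- generate_surface(spec, 8)
  inj <- inject_profilometry_errors(surf, 0.02, seed = 4)
  cleaned <- clean_profile(inj)
  expect_lte(var(as.vector(cleaned$heights)), var(as.vector(inj$heights)))
})

test_that("slope follows the 2x2 cardinal vector-sum rule", {
  expect_equal(max(compute_slope(matrix(3, 8, 8), pitch = 2)), 0)

  # plane rising 10 um/px along rows at 20 um pitch: 50%
  p1 <- outer(1:8 * 10, rep(0, 8), `+`)
  expect_equal(unique(as.vector(compute_slope(p1, pitch = 20))), 50)

  # 3 um/px rows + 4 um/px cols at 10 um pitch: ||(3,4)|| / 10 = 50%
  p2 <- outer(1:8 * 3, 1:8 * 4, `+`)
  expect_equal(unique(as.vector(compute_slope(p2, pitch = 10))), 50)

  expect_error(compute_slope(matrix(1, 1, 5), pitch = 1))
})

test_that("angularity vanishes on planes and is constant on a paraboloid", {
  p <- outer(1:10 * 3, 1:10 * 4, `+`)
  a <- compute_angularity(compute_slope(p, pitch = 10), pitch = 10)
  expect_lt(max(abs(a)), 1e-12)

  # bowl h = c * r^2: |grad| = 2c r, so the second-derivative magnitude
  # field is 2c everywhere away from the apex
  cc <- 0.05; pitch <- 2
  x <- (1:21 - 30) * pitch  # offset so the apex is outside the grid
  bowl <- outer(x^2, x^2, `+`) * cc
  ang <- compute_angularity(compute_slope(bowl, pitch = pitch), pitch = pitch)
  expect_equal(median(ang), 2 * cc, tolerance = 0.05)

  # flat sheet meeting a plane: curvature only at the crease
  crease <- cbind(matrix(0, 10, 5), outer(rep(1, 10), 1:5 * 3))
  ac <- compute_angularity(compute_slope(crease, pitch = 1), pitch = 1)
  expect_true(all(ac[, c(1:2, 6:8)] == 0))
  expect_true(any(ac[, 3:5] > 0))
})

test_that("autocorrelogram matches the direct-sum oracle and is symmetric", {
  set.seed(42)
  h <- matrix(rnorm(8 * 8), 8)
  acg <- autocorrelogram(h)
  expect_equal(acg[8, 8], 1)
  expect_equal(acg, acg[rev(seq_len(15)), rev(seq_len(15))],
               ignore_attr = TRUE)

  hm <- h - mean(h)
  direct <- function(dx, dy) {
    s <- 0
    for (i in 1:8) for (j in 1:8) {
      ii <- i + dx; jj <- j + dy
      if (ii >= 1 && ii <= 8 && jj >= 1 && jj <= 8) s <- s + hm[i, j] * hm[ii, jj]
    }
    s
  }
  c0 <- direct(0, 0)
  for (dx in -3:3) for (dy in -3:3) {
    expect_equal(acg[8 + dx, 8 + dy], direct(dx, dy) / c0, tolerance = 1e-10)
  }

  expect_error(autocorrelogram(matrix(1, 5, 5)), "constant")
})

test_that("correlation length matches closed forms", {
  set.seed(7)
  w <- matrix(rnorm(64 * 64), 64)
  expect_equal(correlation_length(autocorrelogram(w), pitch = 3), 3,
               tolerance = 0.15)

  # Gaussian-smoothed noise: ACF is Gaussian with sd sigma*sqrt(2),
  # FWHM = 2 * sqrt(2 log 2) * sigma * sqrt(2)
  sigma <- 2
  sm <- gaussian_smooth(matrix(rnorm(128 * 128), 128), sigma)
  expected <- 2 * sqrt(2 * log(2)) * sigma * sqrt(2)
  expect_equal(correlation_length(autocorrelogram(sm), pitch = 1), expected,
               tolerance = 0.1)

  # never dropping below half height is an error, not a silent number
  flat_top <- matrix(0.9, 11, 11)
  flat_top[6, 6] <- 1
  expect_error(correlation_length(flat_top, pitch = 1), "lower bound")
})

test_that("spatial spectrum localizes sinusoids and conserves power", {
  n <- 64
  k <- 8 / n  # cycles per pixel
  s <- outer(sin(2 * pi * k * (1:n)), rep(1, n))
  sp <- spatial_spectrum(s, pitch = 1, window = FALSE)
  expect_equal(sp$spectrum$freq[which.max(sp$spectrum$power)], k,
               tolerance = 0.02)
  expect_equal(sp$centroid, k, tolerance = 0.05)

  set.seed(9)
  w <- matrix(rnorm(n * n), n)
  spw <- spatial_spectrum(w, pitch = 1)
  # Parseval: total power equals the windowed grid variance
  wr <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  g <- (w - mean(w)) * outer(wr, wr)
  g <- g - mean(g)
  expect_equal(spw$total_power, mean(g^2), tolerance = 1e-10)
  # flat spectrum: centroid near the middle of the radial band
  expect_equal(spw$centroid, mean(spw$spectrum$freq), tolerance = 0.1)
})

test_that("surface summaries exclude interpolated pixels and normalize", {
  spec <- texture_spec("toy", 40, grid_shape = c(50, 50), pixel_pitch = 4)
  surf <- clean_profile(inject_profilometry_errors(generate_surface(spec, 3),
                                                   0.01, seed = 1))
  sm <- surface_summary(surf)
  expect_equal(sum(sm$height_distribution$p), 1)
  expect_equal(sum(sm$slope_distribution$p), 1)
  expect_equal(sum(sm$angularity_distribution$p), 1)
  expect_gt(sm$correlation_length, 0)
})
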