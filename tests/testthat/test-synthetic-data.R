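test_that("surface generator is deterministic and respects degenerate specs", {
  spec <- texture_spec("toy", 50, grid_shape = c(40, 40), pixel_pitch = 5)
  a <- generate_surface(spec, seed = 11)
  b <- generate_surface(spec, seed = 11)
  expect_identical(a$heights, b$heights)
  expect_gt(sd(a$heights), 0)

  flat_spec <- texture_spec("flat", 50, packing_density = 0,
                            grid_shape = c(20, 20), pixel_pitch = 5)
  expect_warning(flat <- generate_surface(flat_spec, 1), "flat")
  expect_equal(sd(flat$heights), 0)
})

test_that("rough surfaces have longer correlation length than smooth ones", {
  tx <- preset_textures()
  cl80 <- correlation_length(generate_surface(tx$P80, 1))
  cl1200 <- correlation_length(generate_surface(tx$P1200, 1))
  expect_gt(cl80, cl1200)
})

test_that("injected profilometry errors sit in valleys with a far-out sentinel", {
  spec <- texture_spec("toy", 40, grid_shape = c(60, 60), pixel_pitch = 4)
  surf <- generate_surface(spec, 3)

  unchanged <- inject_profilometry_errors(surf, 0, seed = 1)
  expect_identical(unchanged$heights, surf$heights)
  expect_equal(sum(attr(unchanged, "truth_mask")), 0)

  inj <- inject_profilometry_errors(surf, 0.02, seed = 1)
  truth <- attr(inj, "truth_mask")
  expect_equal(sum(truth), round(0.02 * length(surf$heights)))
  # injected pixels come from the lowest-height decile
  q10 <- quantile(surf$heights, 0.1)
  expect_true(all(surf$heights[truth] <= q10))
  # sentinel far below the true data range
  expect_true(all(inj$heights[truth] <
                    min(surf$heights) - 10 * sd(surf$heights)))
})

test_that("noise-free sweeps are exactly linear and slip-free", {
  ctx <- test_context()
  tr <- generate_sweep(ctx, slip_model(rate = 0, noise_sd_accel = 0), 1)
  d <- differentiate(tr)
  expect_equal(max(abs(tr$position - 600 * tr$time)), 0)
  expect_lt(max(abs(d$acceleration)), 1e-5)
  expect_equal(nrow(attr(tr, "truth")), 0)
})

test_that("slip event counts follow the Poisson rate", {
  ctx <- test_context()  # 100 ms sweep at 600 deg/s
  sm <- slip_model(rate = 20, rate_speed_slope = 0, noise_sd_accel = 0)
  counts <- vapply(1:300, function(s) {
    nrow(attr(generate_sweep(ctx, sm, s), "truth"))
  }, numeric(1))
  # rate * duration = 2; placement window and non-overlap thinning shave
  # off a bounded fraction (< ~20%)
  expect_gt(mean(counts), 1.5)
  expect_lt(mean(counts), 2.1)
})

test_that("air sweeps recover the acceleration noise SD and the 2*SD threshold", {
  ctx <- test_context()
  air <- lapply(1:50, function(s) generate_air_sweep(ctx, 1000, seed = s))
  sds <- vapply(air, function(tr) sd(differentiate(tr)$acceleration),
                numeric(1))
  expect_equal(mean(sds), 1000, tolerance = 0.1)
  thr <- calibrate_threshold(air, driving_speed = 600)
  expect_equal(thr, 2000, tolerance = 0.1)

  silent <- generate_air_sweep(ctx, 0, seed = 1)
  expect_lt(max(abs(differentiate(silent)$acceleration)), 1e-5)
})

test_that("make_dataset produces the full labeled design deterministically", {
  tx <- preset_textures()[c("P80", "P1200")]
  sm <- preset_slip_models()[c("P80", "P1200")]
  ctxs <- list(test_context(600), test_context(1200))
  ds <- make_dataset(tx, sm, ctxs, n_cycles = 3, n_air = 2, seed = 5,
                     surfaces = FALSE)
  expect_equal(length(ds$sweeps), 2 * 2 * 3)
  expect_equal(length(ds$air), 2 * 2)
  expect_setequal(unique(vapply(ds$sweeps, `[[`, character(1), "texture")),
                  c("P80", "P1200"))

  ds2 <- make_dataset(tx, sm, ctxs, n_cycles = 3, n_air = 2, seed = 5,
                      surfaces = FALSE)
  expect_identical(ds$sweeps[[7]]$position, ds2$sweeps[[7]]$position)

  dup <- list(test_context(600), test_context(600))
  expect_error(make_dataset(tx, sm, dup, n_cycles = 2, seed = 1),
               "duplicate")
})

test_that("serialized datasets are byte-identical across reruns of one seed", {
  tx <- list(toy = texture_spec("toy", 40, grid_shape = c(20, 20),
                                pixel_pitch = 4))
  sm <- list(toy = slip_model())
  d1 <- file.path(tempdir(), "ds_a"); d2 <- file.path(tempdir(), "ds_b")
  for (d in c(d1, d2)) {
    unlink(d, recursive = TRUE)
    write_dataset(make_dataset(tx, sm, list(test_context()), n_cycles = 2,
                               n_air = 1, seed = 9), d)
  }
  files <- list.files(d1)
  expect_true(length(files) >= 4)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("ground-truth slip rates are recovered from the stored truth lists", {
  ctx <- test_context()
  sm <- slip_model(rate = 30, rate_speed_slope = 0)
  n_sweeps <- 100
  counts <- vapply(1:n_sweeps, function(s) {
    nrow(attr(generate_sweep(ctx, sm, s), "truth"))
  }, numeric(1))
  dur <- sweep_duration(ctx)
  est <- sum(counts) / (n_sweeps * dur)
  # thinning trims a small fraction; estimate must sit within 2 Poisson SE
  # of the thinned expectation, bounded above by the nominal rate
  se <- sqrt(sum(counts)) / (n_sweeps * dur)
  expect_lt(est, 30 + 2 * se)
  expect_gt(est, 30 * 0.75 - 2 * se)
})

test_that("shared slip statistics yield chance-level sa discriminability", {
  tx <- preset_textures()
  shared <- slip_model()
  sm <- lapply(tx, function(x) shared)
  ds <- make_dataset(tx, sm, list(test_context()), n_cycles = 15,
                     n_air = 10, seed = 21, surfaces = FALSE)
  ft <- build_feature_table(ds)
  pa <- pairwise_auc(ft, "sa")
  # Mann-Whitney null SD per pair
  se <- sqrt((pa$n_a + pa$n_b + 1) / (12 * pa$n_a * pa$n_b))
  expect_true(all(abs(pa$auc - 0.5) < 3 * se))
})

test_that("larger peak-acceleration separation raises sa discriminability", {
  ctx <- test_context()
  auc_for_sep <- function(loc_b, seed) {
    sa_a <- sa_b <- c()
    for (k in 1:10) {
      ta <- generate_sweep(ctx, slip_model(peak_accel_location = 20000,
                                           noise_sd_accel = 0),
                           1000 * seed + k)
      tb <- generate_sweep(ctx, slip_model(peak_accel_location = loc_b,
                                           noise_sd_accel = 0),
                           1000 * seed + 100 + k)
      sa_a <- c(sa_a, attr(ta, "truth")$peak_accel)
      sa_b <- c(sa_b, attr(tb, "truth")$peak_accel)
    }
    auc(sa_a, sa_b)
  }
  for (seed in 1:3) {
    a_null <- auc_for_sep(20000, seed)
    a_big <- auc_for_sep(60000, seed)
    expect_gt(a_big, a_null)
  }
})
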