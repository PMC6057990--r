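test_that("differentiation recovers ramps exactly and sinusoids to 2nd order", {
  fs <- 4000
  t <- (0:399) / fs
  ctx <- sweep_context(driving_speed = 600)
  tr <- trajectory_trace(t, 600 * t, ctx)
  d <- differentiate(tr)
  expect_lt(max(abs(d$velocity - 600)), 1e-6)
  expect_lt(max(abs(d$acceleration)), 1e-5)

  A <- 2; f <- 100
  d2 <- differentiate(A * sin(2 * pi * f * t), dt = 1 / fs)
  interior <- 10:390
  expect_equal(max(abs(d2$acceleration[interior])), A * (2 * pi * f)^2,
               tolerance = 0.02)

  expect_error(differentiate(c(1, 2), dt = 1), "3 samples")
})

test_that("trimming removes the artifact window but keeps timestamps", {
  ctx <- sweep_context(driving_speed = 600)  # 100 ms
  tr <- generate_sweep(ctx, slip_model(), 2)
  trt <- trim_protraction(tr, 15)
  expect_equal(diff(range(trt$time)), 0.085, tolerance = 0.001)
  expect_equal(trt$time[1], 0.015)
  expect_identical(trim_protraction(tr, 0), tr)
  expect_error(trim_protraction(tr, 200), "shorter")
})

test_that("events in the trimmed window disappear from the pipeline", {
  fs <- 4000
  ctx <- sweep_context(driving_speed = 600)
  t <- (0:399) / fs
  tau <- 0.005; A <- 30000
  mk_pos <- function(t0) {
    s <- t - t0
    p <- numeric(length(t))
    inside <- s > 0 & s < tau
    k <- A * tau / (2 * pi)
    p[inside] <- k * (s[inside] - tau / (2 * pi) * sin(2 * pi * s[inside] / tau))
    p[s >= tau] <- k * tau
    p
  }
  pos <- 600 * t + mk_pos(0.010) + mk_pos(0.040)
  tr <- trajectory_trace(t, pos, ctx)
  trt <- trim_protraction(tr, 15)
  ev <- detect_slips(trt, threshold = 10000)
  expect_equal(nrow(ev), 1)
  # the peak sample may sit on either lobe of the biphasic pulse
  expect_lt(abs(ev$t_peak - (0.040 + tau / 4)), tau)
})

test_that("the in-air threshold is k times the pooled acceleration SD", {
  ctx <- sweep_context(driving_speed = 600)
  air <- lapply(1:30, function(s) generate_air_sweep(ctx, 1000, seed = s))
  thr <- calibrate_threshold(air, driving_speed = 600)
  expect_equal(thr, 2000, tolerance = 0.1)
  expect_equal(calibrate_threshold(air, driving_speed = 600, k = 0), 0)
  expect_error(calibrate_threshold(air, driving_speed = 1200), "1200")
})

test_that("slip detection applies the threshold-run-merge rule", {
  fs <- 4000
  pulse <- function(A, tau = 0.002) A * sin(2 * pi * seq(0, tau, by = 1 / fs) / tau)

  # single pulse, peak 3x threshold
  acc <- c(numeric(40), pulse(3000), numeric(40))
  ev <- detect_slips(manual_trace(acc), threshold = 1000)
  expect_equal(nrow(ev), 1)
  expect_equal(abs(ev$peak_acceleration), 3000, tolerance = 0.02)

  # all sub-threshold: nothing
  expect_equal(nrow(detect_slips(manual_trace(acc), threshold = 5000)), 0)

  # two bursts 0.5 ms apart merge under a 1 ms gap; 5 ms apart they do not
  burst <- rep(2000, 4)
  gap_small <- numeric(2)   # 0.5 ms
  gap_big <- numeric(20)    # 5 ms
  a1 <- c(numeric(10), burst, gap_small, burst, numeric(10))
  a2 <- c(numeric(10), burst, gap_big, burst, numeric(10))
  expect_equal(nrow(detect_slips(manual_trace(a1), threshold = 1000)), 1)
  expect_equal(nrow(detect_slips(manual_trace(a2), threshold = 1000)), 2)
})

test_that("detection is monotone in the threshold once events are unimodal", {
  # with a merge gap bridging both lobes of each biphasic pulse, every pulse
  # is one event and raising the threshold can only remove events (a gap
  # shorter than the inter-lobe dip would instead split events at high
  # thresholds, where monotonicity genuinely does not hold)
  ctx <- sweep_context(driving_speed = 600)
  tr <- generate_sweep(ctx, slip_model(rate = 40, noise_sd_accel = 0), 4)
  truth <- attr(tr, "truth")
  thresholds <- c(0.1, 0.3, 0.6, 0.9, 1.5) * min(truth$peak_accel)
  counts <- vapply(thresholds, function(th) {
    nrow(detect_slips(tr, th, merge_gap_ms = 3))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], nrow(truth))
  expect_lt(counts[5], nrow(truth))
})

test_that("noise-free slips are recovered one to one with unit gain", {
  ctx <- sweep_context(driving_speed = 600)
  sm <- slip_model(rate = 30, noise_sd_accel = 0)
  det <- c(); tru <- c()
  for (s in 1:30) {
    tr <- generate_sweep(ctx, sm, s)
    truth <- attr(tr, "truth")
    if (!nrow(truth)) next
    ev <- detect_slips(tr, threshold = 0.3 * min(truth$peak_accel))
    expect_equal(nrow(ev), nrow(truth))
    # the detector may land on either lobe of the biphasic pulse
    expect_lt(max(abs(ev$t_peak - truth$t_peak)), sm$pulse_duration)
    det <- c(det, abs(ev$peak_acceleration))
    tru <- c(tru, truth$peak_accel)
  }
  slope <- coef(lm(det ~ 0 + tru))[[1]]
  expect_gt(slope, 0.95)
  expect_lt(slope, 1.05)
})

test_that("slip features compute the rate and tolerate empty event lists", {
  ev <- data.frame(t_peak = c(0.02, 0.04, 0.06),
                   peak_velocity = c(10, 20, 30),
                   peak_acceleration = c(1e4, 2e4, 3e4),
                   duration = rep(0.004, 3))
  sf <- slip_features(ev, 0.075)
  expect_equal(sf$slip_rate, 40)

  empty <- detect_slips(manual_trace(numeric(100)), threshold = 1)
  sf0 <- slip_features(empty, 0.1)
  expect_equal(sf0$slip_rate, 0)
  expect_error(slip_features(ev, 0), "duration")
})

test_that("air sweeps through the pipeline show the Gaussian tail event load", {
  ctx <- sweep_context(driving_speed = 600)
  air <- lapply(1:40, function(s) generate_air_sweep(ctx, 1500, seed = 400 + s))
  thr <- calibrate_threshold(air, driving_speed = 600)
  acc <- unlist(lapply(air, function(tr) {
    differentiate(trim_protraction(tr))$acceleration
  }))
  frac <- mean(abs(acc) > thr)
  # two-sided 2 SD Gaussian tail = 0.0455; band-limited samples are
  # correlated, so use the decorrelated effective sample count (~fs / 2fc)
  n_eff <- length(acc) * (2 * 250) / 4000
  expect_equal(frac, 0.0455, tolerance = 3 * sqrt(0.0455 * 0.9545 / n_eff) / 0.0455)
})
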