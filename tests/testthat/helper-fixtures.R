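# Shared fixtures and independent oracles, built in code at test time.

# Gaussian smoothing by circular FFT convolution with a periodic kernel;
# used to construct fields whose autocorrelation has a closed form.
gaussian_smooth <- function(m, sigma) {
  nr <- nrow(m); nc <- ncol(m)
  kx <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
  ky <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
  k <- exp(-outer(kx^2, ky^2, `+`) / (2 * sigma^2))
  k <- k / sum(k)
  Re(fft(fft(m) * fft(k), inverse = TRUE)) / (nr * nc)
}

# Brute-force all-pairs AUC oracle: count b > a pairs, ties half credit.
brute_auc <- function(a, b) {
  wins <- 0
  for (x in a) for (y in b) {
    wins <- wins + (y > x) + 0.5 * (y == x)
  }
  wins / (length(a) * length(b))
}

# A small standard context/model pair used across kinematics tests.
test_context <- function(speed = 600) sweep_context(driving_speed = speed)

# Position trace for a hand-constructed acceleration profile: passes a
# plain list to detect_slips (time / velocity / acceleration).
manual_trace <- function(acc, fs = 4000, driving = 0) {
  t <- (seq_along(acc) - 1) / fs
  v <- cumsum(acc) / fs
  list(time = t, velocity = v + driving, acceleration = acc,
       driving_speed = driving)
}
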