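#' Trajectory trace container
#'
#' A uniformly sampled angular-position sweep with its context labels.
#'
#' @param time Numeric vector of timestamps, seconds, uniform steps.
#' @param position Numeric vector of angular positions, degrees.
#' @param context A [sweep_context()].
#' @param is_air Logical; `TRUE` for in-air control sweeps (no texture).
#' @param texture Texture label or `NA` for air sweeps.
#' @return An object of class `trajectory_trace`.
#' @export
trajectory_trace <- function(time, position, context, is_air = FALSE,
                             texture = NA_character_) {
  stopifnot(length(time) == length(position), length(time) >= 2,
            inherits(context, "sweep_context"))
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
    stop("trajectory_trace requires uniform sampling", call. = FALSE)
  }
  structure(list(time = time, position = position, context = context,
                 is_air = isTRUE(is_air), texture = texture),
            class = "trajectory_trace")
}

#' @export
print.trajectory_trace <- function(x, ...) {
  cat(sprintf("<trajectory_trace %s%s: %d samples, %.1f ms @ %g deg/s>\n",
              if (x$is_air) "air" else x$texture,
              sprintf(" [%s/%s]", x$context$whisker_id, x$context$distance),
              length(x$time), 1000 * diff(range(x$time)),
              x$context$driving_speed))
  invisible(x)
}

# Band-limited Gaussian noise: white noise low-passed (FFT, hard cutoff at
# `cutoff_hz`) and rescaled to the requested SD. Band-limiting keeps the
# finite-difference second derivative of the integrated trace faithful to the
# noise SD; the marginal distribution stays Gaussian.
band_limited_noise <- function(n, sd_target, fs, cutoff_hz = 250) {
  if (sd_target <= 0) return(numeric(n))
  w <- rnorm(n)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  keep <- f <= cutoff_hz
  x <- Re(fft(fft(w) * keep, inverse = TRUE)) / n
  x * sd_target / sd(x)
}

# Biphasic slip pulse: acceleration A * sin(2*pi*s/tau) on s in [0, tau].
# Closed-form position contribution so traces are exact before numerical
# differentiation. Peak |acceleration| = A at s = tau/4; peak modulation
# velocity = A*tau/pi; net velocity step 0; net forward displacement
# A*tau^2/(2*pi).
pulse_position <- function(t, t0, A, tau) {
  s <- t - t0
  p <- numeric(length(t))
  inside <- s > 0 & s < tau
  after <- s >= tau
  k <- A * tau / (2 * pi)
  p[inside] <- k * (s[inside] - tau / (2 * pi) * sin(2 * pi * s[inside] / tau))
  p[after] <- k * tau                        # = A * tau^2 / (2*pi)
  p
}

#' Generate a synthetic whisker sweep
#'
#' Simulates one protraction: constant driving motion plus a Poisson train of
#' biphasic slip pulses and band-limited acceleration noise, integrated into
#' an angular-position trace. Event times are drawn Poisson at the
#' speed-adjusted rate and thinned so no two pulses overlap (a point on the
#' shaft cannot undergo two simultaneous slips); the surviving ground-truth
#' events (onset, acceleration-peak time, peak acceleration, peak modulation
#' velocity) are attached as attribute `"truth"` for recovery tests.
#'
#' @param ctx A [sweep_context()].
#' @param slip A [slip_model()].
#' @param seed Integer seed; identical seeds give identical traces.
#' @return A [trajectory_trace()] with attribute `truth` (data.frame with
#'   columns `t0`, `t_peak`, `peak_accel`, `peak_vel`).
#' @export
generate_sweep <- function(ctx, slip, seed = 1L) {
  stopifnot(inherits(ctx, "sweep_context"), inherits(slip, "slip_model"))
  dur <- sweep_duration(ctx)
  if (dur <= 0.015) {
    stop("sweep shorter than the 15 ms trim window", call. = FALSE)
  }
  fs <- ctx$sample_rate
  n <- floor(dur * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  tau <- slip$pulse_duration
  out <- with_seed(seed, {
    rate <- max(0, slip$rate + slip$rate_speed_slope * (ctx$driving_speed - 600))
    n_ev <- if (rate > 0) rpois(1, rate * dur) else 0L
    pos <- ctx$driving_speed * t
    truth <- data.frame(t0 = numeric(0), t_peak = numeric(0),
                        peak_accel = numeric(0), peak_vel = numeric(0))
    if (n_ev > 0) {
      t0 <- sort(runif(n_ev, 0, max(dur - tau, 0)))
      # thin pulses that overlap or abut: a shaft point cannot slip twice at
      # once, and a 2 ms guard keeps distinct events from fusing into one
      # suprathreshold run under the default 1 ms detector merge gap
      keep <- c(TRUE, diff(t0) >= tau + 0.002)
      t0 <- t0[keep]
      A <- rlnorm(length(t0), log(slip$peak_accel_location),
                  slip$peak_accel_scale)
      for (j in seq_along(t0)) {
        pos <- pos + pulse_position(t, t0[j], A[j], tau)
      }
      truth <- data.frame(t0 = t0, t_peak = t0 + tau / 4,
                          peak_accel = A, peak_vel = A * tau / pi)
    }
    if (slip$noise_sd_accel > 0) {
      a_noise <- band_limited_noise(n, slip$noise_sd_accel, fs)
      v_noise <- pracma::cumtrapz(t, a_noise)[, 1]
      pos <- pos + pracma::cumtrapz(t, v_noise)[, 1]
    }
    list(pos = pos, truth = truth)
  })
  tr <- trajectory_trace(t, out$pos, ctx, is_air = FALSE)
  attr(tr, "truth") <- out$truth
  tr
}

#' Generate an in-air control sweep
#'
#' Identical to [generate_sweep()] with the slip rate forced to zero: pure
#' driving motion plus acceleration noise. Used to calibrate the 2*SD slip
#' detection threshold.
#'
#' @param ctx A [sweep_context()].
#' @param noise_sd_accel Acceleration noise SD, deg/s^2 (0 gives an exactly
#'   linear ramp).
#' @param seed Integer seed.
#' @return A [trajectory_trace()] with `is_air = TRUE`.
#' @export
generate_air_sweep <- function(ctx, noise_sd_accel = 2000, seed = 1L) {
  m <- slip_model(rate = 0, noise_sd_accel = noise_sd_accel)
  tr <- generate_sweep(ctx, m, seed)
  tr$is_air <- TRUE
  tr
}

#' Generate a full labeled dataset
#'
#' Builds a reproducible bundle of texture sweeps, in-air controls and
#' synthetic surface grids: for every context and texture, `n_cycles` sweeps
#' driven by that texture's slip model, plus `n_air` air sweeps per context.
#' Child seeds are derived deterministically from `seed` by a counter scheme,
#' so the dataset is fully reproducible.
#'
#' @param textures Named list of [texture_spec()] objects.
#' @param slip_models Named list of [slip_model()] objects, names matching
#'   `textures`.
#' @param contexts List of [sweep_context()] objects (must be distinct in
#'   whisker/speed/distance).
#' @param n_cycles Sweeps per texture x context (default 100, the standard
#'   measurement protocol).
#' @param n_air Air control sweeps per context (default 20).
#' @param seed Master integer seed.
#' @param surfaces Logical; also generate a surface grid per texture.
#' @return An object of class `slip_dataset`: list with elements `sweeps`
#'   (list of [trajectory_trace()]), `air` (list), `surfaces` (named list of
#'   [height_profile()] or `NULL`), `textures`, `slip_models`, `contexts`,
#'   `n_cycles`, `seed`.
#' @export
make_dataset <- function(textures = preset_textures(),
                         slip_models = preset_slip_models(),
                         contexts = list(sweep_context()),
                         n_cycles = 100L, n_air = 20L, seed = 1L,
                         surfaces = TRUE) {
  stopifnot(n_cycles >= 1, n_air >= 1,
            all(names(textures) %in% names(slip_models)))
  ckey <- vapply(contexts, function(cx) {
    paste(cx$whisker_id, cx$driving_speed, cx$distance, sep = "|")
  }, character(1))
  if (anyDuplicated(ckey)) stop("duplicate condition keys in `contexts`")
  counter <- 0L
  nxt <- function() {
    counter <<- counter + 1L
    child_seed(seed, counter)
  }
  sweeps <- list(); air <- list()
  for (ci in seq_along(contexts)) {
    ctx <- contexts[[ci]]
    for (tx in names(textures)) {
      for (cyc in seq_len(n_cycles)) {
        tr <- generate_sweep(ctx, slip_models[[tx]], nxt())
        tr$texture <- tx
        sweeps[[length(sweeps) + 1L]] <- tr
      }
    }
    noise_sd <- max(vapply(slip_models, `[[`, numeric(1), "noise_sd_accel"))
    for (cyc in seq_len(n_air)) {
      air[[length(air) + 1L]] <- generate_air_sweep(ctx, noise_sd, nxt())
    }
  }
  surf <- NULL
  if (surfaces) {
    surf <- lapply(names(textures), function(tx) {
      generate_surface(textures[[tx]], nxt())
    })
    names(surf) <- names(textures)
  }
  structure(list(sweeps = sweeps, air = air, surfaces = surf,
                 textures = textures, slip_models = slip_models,
                 contexts = contexts, n_cycles = as.integer(n_cycles),
                 seed = as.integer(seed)),
            class = "slip_dataset")
}

#' @export
print.slip_dataset <- function(x, ...) {
  cat(sprintf("<slip_dataset: %d sweeps, %d air controls, %d textures, %d contexts, seed %d>\n",
              length(x$sweeps), length(x$air), length(x$textures),
              length(x$contexts), x$seed))
  invisible(x)
}
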