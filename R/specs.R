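#' Texture specification
#'
#' Describes a sandpaper-like texture for the synthetic surface generator:
#' grains are modeled as spherical caps with diameters drawn around
#' `grain_diameter_mean` at coefficient of variation `grain_diameter_cv`,
#' packed at `packing_density` grains per square micrometer.
#'
#' @param name Texture label (e.g. `"P80"`).
#' @param grain_diameter_mean Mean grain diameter, micrometers (> 0).
#' @param grain_diameter_cv Coefficient of variation of grain diameter,
#'   in (0, 1).
#' @param packing_density Grains per square micrometer (>= 0).
#' @param grid_shape Integer vector of length 2, pixels (rows, cols).
#' @param pixel_pitch Micrometers per pixel (> 0).
#'
#' @return An object of class `texture_spec`.
#' @seealso [preset_textures()] for the five standard sandpapers.
#' @export
texture_spec <- function(name, grain_diameter_mean, grain_diameter_cv = 0.25,
                         packing_density = NULL,
                         grid_shape = c(200L, 200L), pixel_pitch = NULL) {
  stopifnot(grain_diameter_mean > 0,
            grain_diameter_cv > 0, grain_diameter_cv < 1,
            length(grid_shape) == 2, all(grid_shape > 0))
  if (is.null(pixel_pitch)) pixel_pitch <- grain_diameter_mean / 10
  stopifnot(pixel_pitch > 0)
  if (is.null(packing_density)) {
    # tight packing: ~2 grains per mean-diameter square
    packing_density <- 2 / grain_diameter_mean^2
  }
  stopifnot(packing_density >= 0)
  structure(list(name = as.character(name),
                 grain_diameter_mean = grain_diameter_mean,
                 grain_diameter_cv = grain_diameter_cv,
                 packing_density = packing_density,
                 grid_shape = as.integer(grid_shape),
                 pixel_pitch = pixel_pitch),
            class = "texture_spec")
}

#' Preset sandpaper textures
#'
#' The five standard-series sandpapers P80, P240, P400, P600 and P1200 with
#' mean grain diameters 201, 58.5, 35.0, 25.8 and 15.3 micrometers. Profiles
#' are 200 x 200 pixels spanning 4000, 1700, 1000, 700 and 500 micrometers on
#' a side respectively, giving pixel pitches of 20, 8.5, 5, 3.5 and 2.5
#' micrometers.
#'
#' @return Named list of [texture_spec()] objects, roughest first.
#' @export
preset_textures <- function() {
  names <- c("P80", "P240", "P400", "P600", "P1200")
  diam <- c(201, 58.5, 35.0, 25.8, 15.3)
  side <- c(4000, 1700, 1000, 700, 500)
  out <- lapply(seq_along(names), function(k) {
    texture_spec(names[k], grain_diameter_mean = diam[k],
                 grid_shape = c(200L, 200L), pixel_pitch = side[k] / 200)
  })
  names(out) <- names
  out
}

#' Sweep context
#'
#' Contextual labels of one whisker protraction sweep: whisker identity,
#' driving speed of the motor, follicle-to-texture distance class, sampling
#' rate and total sweep angle. The sweep duration is
#' `sweep_angle / driving_speed`.
#'
#' @param whisker_id Whisker label (e.g. `"B"` (beta), `"C2"`).
#' @param driving_speed Imposed rotation speed, deg/s (600, 1200 or 1800 in
#'   the standard design; any positive value accepted).
#' @param distance Distance class, one of `"H"`, `"Q"`, `"F"` (half,
#'   three-quarter, full-minus-5mm whisker length).
#' @param sample_rate Samples per second (default 4000).
#' @param sweep_angle Total protraction angle, degrees (default 60).
#'
#' @return An object of class `sweep_context`.
#' @export
sweep_context <- function(whisker_id = "B", driving_speed = 600,
                          distance = c("H", "Q", "F"),
                          sample_rate = 4000, sweep_angle = 60) {
  distance <- match.arg(distance)
  stopifnot(driving_speed > 0, sample_rate > 0, sweep_angle > 0)
  structure(list(whisker_id = as.character(whisker_id),
                 driving_speed = driving_speed,
                 distance = distance,
                 sample_rate = sample_rate,
                 sweep_angle = sweep_angle),
            class = "sweep_context")
}

#' Duration of a sweep in seconds
#' @param ctx A [sweep_context()].
#' @return Sweep duration in seconds (`sweep_angle / driving_speed`).
#' @export
sweep_duration <- function(ctx) ctx$sweep_angle / ctx$driving_speed

#' Stochastic slip model
#'
#' Statistical description of the stick-slip transients superimposed on the
#' driving motion: a Poisson train of brief biphasic acceleration pulses whose
#' peak accelerations follow a lognormal (heavy right tail) distribution, plus
#' band-limited Gaussian acceleration noise.
#'
#' The event rate is speed-coupled: at driving speed `v` the effective rate is
#' `max(0, rate + rate_speed_slope * (v - 600))`. The default slope of
#' -2.65/600 events/s per deg/s reproduces the observed mean slip-rate
#' decrement of 2.65 events/s per 600 deg/s speed step.
#'
#' @param rate Baseline slip rate at 600 deg/s driving speed, events/s (>= 0).
#' @param rate_speed_slope Change in rate per deg/s of driving speed.
#' @param peak_accel_location Median of the lognormal peak-acceleration
#'   distribution, deg/s^2.
#' @param peak_accel_scale Lognormal sigma (dimensionless).
#' @param pulse_duration Slip pulse duration, seconds (default 5 ms).
#' @param noise_sd_accel SD of the acceleration noise floor, deg/s^2 (> 0
#'   unless exactly 0 for noise-free traces).
#'
#' @return An object of class `slip_model`.
#' @export
slip_model <- function(rate = 50, rate_speed_slope = -2.65 / 600,
                       peak_accel_location = 25000, peak_accel_scale = 0.3,
                       pulse_duration = 0.005, noise_sd_accel = 2000) {
  stopifnot(rate >= 0, pulse_duration > 0, noise_sd_accel >= 0,
            peak_accel_location > 0, peak_accel_scale >= 0)
  structure(list(rate = rate, rate_speed_slope = rate_speed_slope,
                 peak_accel_location = peak_accel_location,
                 peak_accel_scale = peak_accel_scale,
                 pulse_duration = pulse_duration,
                 noise_sd_accel = noise_sd_accel),
            class = "slip_model")
}

#' Default texture-to-slip-model mapping
#'
#' A plausible assignment of slip statistics to the five preset sandpapers:
#' rougher textures elicit stronger slips (higher median peak acceleration).
#' Baseline rates and the speed coupling are shared. The spacing of the peak
#' acceleration medians is supra-threshold relative to the 23600 deg/s^2
#' acceleration change threshold only across non-adjacent textures, while the
#' induced intensity and best-frequency differences remain far below the 450
#' deg/s and 36 Hz thresholds — the regime the blurred-classifier comparison
#' probes.
#'
#' @param noise_sd_accel Shared acceleration noise SD, deg/s^2.
#' @return Named list of [slip_model()] objects, one per preset texture.
#' @export
preset_slip_models <- function(noise_sd_accel = 2000) {
  loc <- c(P80 = 40000, P240 = 30000, P400 = 22000,
           P600 = 16000, P1200 = 12000)
  lapply(loc, function(m) {
    slip_model(peak_accel_location = m, noise_sd_accel = noise_sd_accel)
  })
}

#' @export
print.texture_spec <- function(x, ...) {
  cat(sprintf("<texture_spec %s: grain %.1f um (cv %.2f), %d x %d px @ %.2f um/px>\n",
              x$name, x$grain_diameter_mean, x$grain_diameter_cv,
              x$grid_shape[1], x$grid_shape[2], x$pixel_pitch))
  invisible(x)
}

#' @export
print.sweep_context <- function(x, ...) {
  cat(sprintf("<sweep_context %s %g deg/s %s, %g deg @ %g Hz (%.1f ms)>\n",
              x$whisker_id, x$driving_speed, x$distance, x$sweep_angle,
              x$sample_rate, 1000 * sweep_duration(x)))
  invisible(x)
}
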