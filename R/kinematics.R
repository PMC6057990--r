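#' Differentiate a position trace
#'
#' Velocity and acceleration by central differences in the interior and
#' one-sided differences at the edges (second-order accurate interior).
#'
#' @param trace A [trajectory_trace()], or numeric position vector with `dt`.
#' @param dt Sample interval, seconds (for vector input).
#' @return List with `velocity` (deg/s) and `acceleration` (deg/s^2), each
#'   the same length as the position vector.
#' @export
differentiate <- function(trace, dt = NULL) {
  if (inherits(trace, "trajectory_trace")) {
    dt <- trace$time[2] - trace$time[1]
    pos <- trace$position
  } else {
    pos <- trace
    stopifnot(is.numeric(dt), dt > 0)
  }
  if (length(pos) < 3) stop("need at least 3 samples to differentiate")
  v <- pracma::gradient(pos, dt)
  a <- pracma::gradient(v, dt)
  list(velocity = v, acceleration = a)
}

#' Trim the start-of-protraction artifact window
#'
#' Removes the first `cut_ms` milliseconds of a sweep (turning artifacts at
#' movement onset); original timestamps are preserved.
#'
#' @param trace A [trajectory_trace()].
#' @param cut_ms Milliseconds to remove from the start (default 15).
#' @return The trimmed [trajectory_trace()] (truth events inside the cut
#'   window are dropped from the `truth` attribute if present).
#' @export
trim_protraction <- function(trace, cut_ms = 15) {
  stopifnot(inherits(trace, "trajectory_trace"), cut_ms >= 0)
  if (cut_ms == 0) return(trace)
  t0 <- trace$time[1] + cut_ms / 1000
  keep <- trace$time >= t0
  if (sum(keep) < 3) stop("trace shorter than the trim window")
  out <- trajectory_trace(trace$time[keep], trace$position[keep],
                          trace$context, trace$is_air, trace$texture)
  tru <- attr(trace, "truth")
  if (!is.null(tru)) attr(out, "truth") <- tru[tru$t_peak >= t0, , drop = FALSE]
  out
}

#' Calibrate the slip detection threshold from in-air controls
#'
#' The slip criterion is `k` times the standard deviation of the pooled
#' acceleration samples observed when the whisker moves in air (no contact,
#' hence no slips), computed separately per driving speed: only air traces
#' whose context matches `driving_speed` are pooled. Traces are trimmed with
#' [trim_protraction()] before pooling.
#'
#' @param air_traces List of in-air [trajectory_trace()] objects.
#' @param driving_speed Driving speed (deg/s) whose controls to use; `NULL`
#'   pools all air traces.
#' @param k Multiplier of the SD (default 2).
#' @param cut_ms Trim window, ms (default 15).
#' @return Threshold in deg/s^2.
#' @export
calibrate_threshold <- function(air_traces, driving_speed = NULL, k = 2,
                                cut_ms = 15) {
  stopifnot(is.list(air_traces), length(air_traces) >= 1)
  if (!is.null(driving_speed)) {
    air_traces <- Filter(function(tr) {
      tr$context$driving_speed == driving_speed
    }, air_traces)
    if (!length(air_traces)) {
      stop(sprintf("no air control traces for driving speed %g deg/s",
                   driving_speed))
    }
  }
  acc <- unlist(lapply(air_traces, function(tr) {
    differentiate(trim_protraction(tr, cut_ms))$acceleration
  }))
  k * sd(acc)
}

#' Detect stick-slip events in an acceleration trace
#'
#' Candidate events are contiguous runs of samples whose absolute
#' acceleration exceeds the threshold; runs separated by less than
#' `merge_gap_ms` are merged into one event. For each event, the sample of
#' maximum absolute acceleration defines the event time and peak
#' acceleration; peak velocity is the maximum absolute modulation velocity
#' (driving speed subtracted by default) within the event window.
#'
#' @param trace A trimmed [trajectory_trace()], or a list with elements
#'   `time`, `velocity`, `acceleration` and `driving_speed`.
#' @param threshold Detection threshold, deg/s^2 (> 0), from
#'   [calibrate_threshold()].
#' @param merge_gap_ms Runs closer than this are merged (default 1 ms).
#' @param two_sided Use |acceleration| (default) or positive-going only.
#' @param subtract_driving Subtract the driving speed before measuring peak
#'   velocity (default `TRUE`).
#' @return data.frame of slip events: `t_peak` (s), `peak_velocity` (deg/s),
#'   `peak_acceleration` (deg/s^2), `duration` (s). Zero rows if no event.
#' @export
detect_slips <- function(trace, threshold, merge_gap_ms = 1,
                         two_sided = TRUE, subtract_driving = TRUE) {
  stopifnot(threshold > 0)
  if (inherits(trace, "trajectory_trace")) {
    d <- differentiate(trace)
    tm <- trace$time
    vel <- d$velocity
    acc <- d$acceleration
    drv <- trace$context$driving_speed
  } else {
    tm <- trace$time; vel <- trace$velocity; acc <- trace$acceleration
    drv <- if (!is.null(trace$driving_speed)) trace$driving_speed else 0
  }
  a_test <- if (two_sided) abs(acc) else acc
  v_mod <- if (subtract_driving) vel - drv else vel
  over <- a_test > threshold
  empty <- data.frame(t_peak = numeric(0), peak_velocity = numeric(0),
                      peak_acceleration = numeric(0), duration = numeric(0))
  if (!any(over)) return(empty)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  dt <- tm[2] - tm[1]
  gap <- merge_gap_ms / 1000
  # merge runs separated by < gap
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      sep <- (runs$start[i] - merged$end[nrow(merged)] - 1L) * dt
      if (sep < gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  ev <- lapply(seq_len(nrow(merged)), function(i) {
    idx <- merged$start[i]:merged$end[i]
    pk <- idx[which.max(a_test[idx])]
    data.frame(t_peak = tm[pk],
               peak_velocity = max(abs(v_mod[idx])),
               peak_acceleration = acc[pk],
               duration = length(idx) * dt)
  })
  do.call(rbind, ev)
}

#' Per-sweep slip features
#'
#' Aggregates detected events into the slip rate `sr` (events per second of
#' analyzed sweep) and keeps the per-event peak velocity (`sv`) and peak
#' acceleration (`sa`) samples for distribution-level pooling.
#'
#' @param events data.frame from [detect_slips()].
#' @param analyzed_duration Duration of the analyzed (trimmed) sweep, s.
#' @return An object of class `sweep_slip_features`: list with `slip_events`,
#'   `slip_rate` (events/s) and `analyzed_duration`.
#' @export
slip_features <- function(events, analyzed_duration) {
  stopifnot(is.data.frame(events), analyzed_duration > 0)
  structure(list(slip_events = events,
                 slip_rate = nrow(events) / analyzed_duration,
                 analyzed_duration = analyzed_duration),
            class = "sweep_slip_features")
}
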