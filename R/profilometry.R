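#' Detect sentinel measurement artifacts in a height grid
#'
#' Optical profilometry of deep valleys occasionally fails and the instrument
#' records an extreme sentinel value. Such pixels are flagged by a conjunction
#' of two rules: the height is an extreme low outlier (below
#' `Q1 - iqr_mult * IQR` of the height distribution) AND the local slope to
#' neighboring pixels exceeds the 95th percentile of the neighbor-slope field,
#' which separates true sentinel errors from genuinely low surface points.
#' The 8-neighbors of every detected pixel are flagged as well, since values
#' adjacent to an error bin are unreliable.
#'
#' @param heights Numeric matrix of heights (um), at least 3 x 3, or a
#'   [height_profile()].
#' @param pitch Micrometers per pixel (ignored if `heights` is a profile).
#' @param iqr_mult Multiple of the IQR below the first quartile that defines
#'   an extreme value (default 5).
#' @param slope_quantile Quantile of the neighbor-slope field that the local
#'   slope must exceed (default 0.95).
#' @return Logical matrix: `TRUE` for pixels to remove (detected errors plus
#'   their 8-neighborhoods). The pre-dilation detections are attached as
#'   attribute `"core"`.
#' @export
detect_artifacts <- function(heights, pitch = NULL, iqr_mult = 5,
                             slope_quantile = 0.95) {
  if (inherits(heights, "height_profile")) {
    pitch <- heights$pixel_pitch
    heights <- heights$heights
  }
  stopifnot(is.matrix(heights), nrow(heights) >= 3, ncol(heights) >= 3,
            is.numeric(pitch), pitch > 0)
  q <- quantile(heights, c(0.25, 0.75), names = FALSE)
  lo <- q[1] - iqr_mult * (q[2] - q[1])
  extreme <- heights < lo
  nb_slope <- neighbor_slope(heights, pitch)
  # percentile of the slope field taken over the uncontaminated bulk:
  # pixels not adjacent to an extreme value, so a few percent of sentinel
  # errors cannot drag the threshold up to sentinel-slope magnitudes
  bulk <- !dilate8(extreme)
  thr <- quantile(if (any(bulk)) nb_slope[bulk] else nb_slope,
                  slope_quantile, names = FALSE)
  core <- extreme & (nb_slope > thr)
  mask <- dilate8(core)
  if (all(mask)) stop("all pixels flagged as artifacts: corrupt input")
  attr(mask, "core") <- core
  mask
}

# Max absolute height difference to any 8-neighbor, per unit distance.
neighbor_slope <- function(h, pitch) {
  nr <- nrow(h); nc <- ncol(h)
  out <- matrix(0, nr, nc)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in shifts) {
    di <- s[1]; dj <- s[2]
    ri <- max(1, 1 + di):min(nr, nr + di)
    rj <- max(1, 1 + dj):min(nc, nc + dj)
    d <- abs(h[ri, rj, drop = FALSE] - h[ri - di, rj - dj, drop = FALSE]) /
      (pitch * sqrt(di^2 + dj^2))
    out[ri, rj] <- pmax(out[ri, rj, drop = FALSE], d)
  }
  out
}

# 8-neighborhood binary dilation.
dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ri <- max(1, 1 + di):min(nr, nr + di)
    rj <- max(1, 1 + dj):min(nc, nc + dj)
    out[ri, rj] <- out[ri, rj] | m[ri - di, rj - dj]
  }
  out
}

#' Linearly interpolate masked pixels of a height grid
#'
#' Replaces each masked pixel by the average of two independent 1D linear
#' interpolations from the nearest valid neighbors along its row and along
#' its column (nearest-value extension at grid edges). If one direction has
#' no valid pixel at all, the other alone is used; a pixel valid in neither
#' direction is an error.
#'
#' @param heights Numeric matrix or [height_profile()].
#' @param mask Logical matrix from [detect_artifacts()].
#' @param pitch Micrometers per pixel (ignored for profiles).
#' @return A [height_profile()] whose `artifact_mask` records the
#'   interpolated pixels.
#' @export
interpolate_artifacts <- function(heights, mask, pitch = NULL) {
  if (inherits(heights, "height_profile")) {
    pitch <- heights$pixel_pitch
    heights <- heights$heights
  }
  stopifnot(identical(dim(mask), dim(heights)), is.numeric(pitch), pitch > 0)
  if (!any(mask)) return(height_profile(heights, pitch, mask))
  interp_lines <- function(h, m) {
    # interpolate along columns of h (i.e. within each row vector)
    t(vapply(seq_len(nrow(h)), function(i) {
      hv <- h[i, ]; mv <- m[i, ]
      if (all(mv)) return(rep(NA_real_, length(hv)))
      if (!any(mv)) return(hv)
      xs <- which(!mv)
      hv[mv] <- approx(xs, hv[xs], xout = which(mv), rule = 2)$y
      hv
    }, numeric(ncol(h))))
  }
  by_row <- interp_lines(heights, mask)
  by_col <- t(interp_lines(t(heights), t(mask)))
  filled <- heights
  est <- ifelse(is.na(by_row), by_col,
                ifelse(is.na(by_col), by_row, (by_row + by_col) / 2))
  if (any(is.na(est[mask]))) {
    stop("masked pixel with no valid neighbor in its row or column")
  }
  filled[mask] <- est[mask]
  height_profile(filled, pitch, mask)
}

#' Clean a height profile
#'
#' Convenience wrapper: [detect_artifacts()] then [interpolate_artifacts()].
#'
#' @param profile A [height_profile()].
#' @param ... Passed to [detect_artifacts()].
#' @return A cleaned [height_profile()] with its `artifact_mask` set.
#' @export
clean_profile <- function(profile, ...) {
  mask <- detect_artifacts(profile, ...)
  interpolate_artifacts(profile, mask)
}

#' Surface slope field
#'
#' First spatial derivative of the height field by a moving 2 x 2 window:
#' within each window the two differences along rows and the two along
#' columns are averaged, and the length of the vector sum of the two cardinal
#' difference vectors, divided by the pixel pitch, gives the slope. Direction
#' is ignored (absolute value); the result is expressed in percent rise/run.
#'
#' @param profile A [height_profile()] (cleaned) or numeric matrix.
#' @param pitch Micrometers per pixel (for matrix input).
#' @param percent Return percent (default) or dimensionless rise/run.
#' @return Slope matrix of size (n-1) x (m-1), with attribute
#'   `"valid"`: logical matrix, `FALSE` where the 2 x 2 support touches an
#'   interpolated pixel.
#' @export
compute_slope <- function(profile, pitch = NULL, percent = TRUE) {
  mask <- NULL
  if (inherits(profile, "height_profile")) {
    pitch <- profile$pixel_pitch
    mask <- profile$artifact_mask
    profile <- profile$heights
  }
  h <- profile
  stopifnot(is.matrix(h), nrow(h) >= 2, ncol(h) >= 2,
            is.numeric(pitch), pitch > 0)
  nr <- nrow(h); nc <- ncol(h)
  i <- seq_len(nr - 1); j <- seq_len(nc - 1)
  drow <- ((h[i + 1, j, drop = FALSE] - h[i, j, drop = FALSE]) +
           (h[i + 1, j + 1, drop = FALSE] - h[i, j + 1, drop = FALSE])) / 2
  dcol <- ((h[i, j + 1, drop = FALSE] - h[i, j, drop = FALSE]) +
           (h[i + 1, j + 1, drop = FALSE] - h[i + 1, j, drop = FALSE])) / 2
  s <- sqrt(drow^2 + dcol^2) / pitch
  if (percent) s <- s * 100
  valid <- matrix(TRUE, nr - 1, nc - 1)
  if (!is.null(mask) && any(mask)) {
    valid <- !(mask[i, j, drop = FALSE] | mask[i + 1, j, drop = FALSE] |
               mask[i, j + 1, drop = FALSE] | mask[i + 1, j + 1, drop = FALSE])
  }
  attr(s, "valid") <- valid
  s
}

#' Surface angularity field
#'
#' Second spatial derivative: the identical 2 x 2 cardinal-difference
#' vector-sum operator applied to the (dimensionless rise/run) slope field,
#' yielding absolute angularity in 1/um. For the height grid of size n x m
#' the result is (n-2) x (m-2).
#'
#' @param slope_grid Slope matrix from [compute_slope()] (percent or
#'   dimensionless; governed by `percent`), or a [height_profile()] from
#'   which the slope is computed first.
#' @param pitch Micrometers per pixel.
#' @param percent Is `slope_grid` in percent? (default `TRUE`).
#' @return Angularity matrix, 1/um, with attribute `"valid"` excluding
#'   windows touching interpolated pixels.
#' @export
compute_angularity <- function(slope_grid, pitch = NULL, percent = TRUE) {
  if (inherits(slope_grid, "height_profile")) {
    pitch <- slope_grid$pixel_pitch
    slope_grid <- compute_slope(slope_grid, percent = FALSE)
    percent <- FALSE
  }
  stopifnot(is.matrix(slope_grid), is.numeric(pitch), pitch > 0)
  valid_in <- attr(slope_grid, "valid")
  s <- if (percent) slope_grid / 100 else slope_grid
  a <- compute_slope(unclass(s), pitch = pitch, percent = FALSE)
  valid <- attr(a, "valid")
  if (!is.null(valid_in)) {
    nr <- nrow(s); nc <- ncol(s)
    i <- seq_len(nr - 1); j <- seq_len(nc - 1)
    valid <- valid_in[i, j, drop = FALSE] & valid_in[i + 1, j, drop = FALSE] &
      valid_in[i, j + 1, drop = FALSE] & valid_in[i + 1, j + 1, drop = FALSE]
  }
  attr(a, "valid") <- valid
  a
}
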