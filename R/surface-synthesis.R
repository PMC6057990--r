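#' Height profile container
#'
#' A 2D grid of surface heights (micrometers) with its pixel pitch and a
#' logical artifact mask marking pixels that were removed and interpolated.
#'
#' @param heights Numeric matrix of heights, micrometers.
#' @param pixel_pitch Micrometers per pixel (> 0).
#' @param artifact_mask Logical matrix, same shape as `heights`; `TRUE` marks
#'   removed-and-interpolated pixels. Defaults to all-`FALSE`.
#'
#' @return An object of class `height_profile`.
#' @export
height_profile <- function(heights, pixel_pitch, artifact_mask = NULL) {
  heights <- as.matrix(heights)
  stopifnot(is.numeric(heights), pixel_pitch > 0)
  if (is.null(artifact_mask)) {
    artifact_mask <- matrix(FALSE, nrow(heights), ncol(heights))
  }
  stopifnot(identical(dim(artifact_mask), dim(heights)))
  structure(list(heights = heights, pixel_pitch = pixel_pitch,
                 artifact_mask = artifact_mask),
            class = "height_profile")
}

#' @export
print.height_profile <- function(x, ...) {
  cat(sprintf("<height_profile %d x %d px @ %.2f um/px, %d masked, height SD %.2f um>\n",
              nrow(x$heights), ncol(x$heights), x$pixel_pitch,
              sum(x$artifact_mask), stats::sd(x$heights)))
  invisible(x)
}

#' Generate a synthetic sandpaper-like surface
#'
#' Builds a height grid by superposing randomly placed spherical-cap grains.
#' Grain diameters are lognormal around `spec$grain_diameter_mean` with the
#' requested coefficient of variation; the surface height at each pixel is the
#' maximum over all overlapping caps (tightly packed abrasive). The number of
#' grains is `packing_density * area`, at least 1 unless density is 0.
#'
#' @param spec A [texture_spec()].
#' @param seed Integer seed; identical seeds give identical grids.
#' @return A [height_profile()].
#' @export
generate_surface <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "texture_spec"))
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  pitch <- spec$pixel_pitch
  area <- (nr * pitch) * (nc * pitch)
  n_grains <- round(spec$packing_density * area)
  if (n_grains < 1) {
    warning("degenerate texture_spec (no grains): returning flat surface")
    return(height_profile(matrix(0, nr, nc), pitch))
  }
  h <- with_seed(seed, {
    # lognormal with mean = grain_diameter_mean and CV = grain_diameter_cv
    cv <- spec$grain_diameter_cv
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(spec$grain_diameter_mean) - sdlog^2 / 2
    diam <- rlnorm(n_grains, meanlog, sdlog)
    cx <- runif(n_grains, 0, nr * pitch)
    cy <- runif(n_grains, 0, nc * pitch)
    x <- (seq_len(nr) - 0.5) * pitch
    y <- (seq_len(nc) - 0.5) * pitch
    h <- matrix(0, nr, nc)
    for (g in seq_len(n_grains)) {
      r <- diam[g] / 2
      ix <- which(abs(x - cx[g]) < r)
      iy <- which(abs(y - cy[g]) < r)
      if (!length(ix) || !length(iy)) next
      d2 <- outer((x[ix] - cx[g])^2, (y[iy] - cy[g])^2, `+`)
      cap <- sqrt(pmax(r^2 - d2, 0))
      h[ix, iy] <- pmax(h[ix, iy], cap)
    }
    h
  })
  height_profile(h, pitch)
}

#' Inject localized profilometry errors into a surface
#'
#' Emulates the optical-profilometer failure mode in which measurements in
#' the deepest valleys are replaced by an extreme sentinel value far below the
#' data range. A fraction of pixels is drawn preferentially from the
#' lowest-height decile and set to `min(heights) - 20 * SD(heights)`. The
#' ground-truth error mask is attached as attribute `"truth_mask"` for
#' validating the artifact detector.
#'
#' @param profile A [height_profile()].
#' @param error_fraction Fraction of pixels to corrupt, in [0, 0.1).
#' @param seed Integer seed.
#' @return A [height_profile()] with sentinel-corrupted heights and attribute
#'   `truth_mask` (logical matrix of injected pixels).
#' @export
inject_profilometry_errors <- function(profile, error_fraction, seed = 1L) {
  stopifnot(inherits(profile, "height_profile"),
            error_fraction >= 0, error_fraction < 0.1)
  h <- profile$heights
  truth <- matrix(FALSE, nrow(h), ncol(h))
  if (error_fraction > 0) {
    n_err <- round(error_fraction * length(h))
    idx <- with_seed(seed, {
      # candidates: lowest-height decile (at least 3x the needed count)
      q <- quantile(h, max(0.1, min(1, 3 * error_fraction)))
      cand <- which(h <= q)
      sample(cand, min(n_err, length(cand)))
    })
    sentinel <- min(h) - 20 * max(sd(h), 1)
    h[idx] <- sentinel
    truth[idx] <- TRUE
  }
  out <- height_profile(h, profile$pixel_pitch, profile$artifact_mask)
  attr(out, "truth_mask") <- truth
  out
}
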