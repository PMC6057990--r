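#' Spatial autocorrelogram of a height grid
#'
#' Normalized 2D autocorrelation of the mean-subtracted height field,
#' computed by the zero-padded FFT method (equivalent to the direct
#' double-sum over all lags with zero outside the grid). The central value
#' (zero lag) is 1; the output spans lags -(n-1)..(n-1) in each dimension
#' with the center at index (n, m).
#'
#' @param profile A [height_profile()] or numeric matrix.
#' @return Numeric matrix of size (2n-1) x (2m-1), central value 1, with
#'   attribute `"pitch"` when available.
#' @export
autocorrelogram <- function(profile) {
  pitch <- NULL
  if (inherits(profile, "height_profile")) {
    pitch <- profile$pixel_pitch
    profile <- profile$heights
  }
  h <- profile - mean(profile)
  if (sd(h) == 0) stop("constant grid: autocorrelation undefined")
  nr <- nrow(h); nc <- ncol(h)
  pr <- 2 * nr - 1; pc <- 2 * nc - 1
  hp <- matrix(0, pr, pc)
  hp[seq_len(nr), seq_len(nc)] <- h
  FT <- fft(hp)
  ac <- Re(fft(FT * Conj(FT), inverse = TRUE)) / (pr * pc)
  # wrap lags so the zero lag sits at the center (nr, nc)
  ac <- ac[c((nr + 1):pr, 1:nr), c((nc + 1):pc, 1:nc)]
  ac <- ac / ac[nr, nc]
  attr(ac, "pitch") <- pitch
  ac
}

# Radial average of a centered 2D field into 1-pixel annular bins.
# Returns data.frame(r = bin radius in pixels, value = mean, n = count).
radial_profile <- function(m, center) {
  nr <- nrow(m); nc <- ncol(m)
  dx <- (seq_len(nr) - center[1])
  dy <- (seq_len(nc) - center[2])
  r <- sqrt(outer(dx^2, dy^2, `+`))
  bin <- round(r)
  agg <- tapply(as.vector(m), as.vector(bin), mean)
  cnt <- tapply(as.vector(m), as.vector(bin), length)
  data.frame(r = as.numeric(names(agg)), value = as.numeric(agg),
             n = as.integer(cnt))
}

#' Correlation length of a surface
#'
#' Full width at half height of the central peak of the radially averaged
#' autocorrelogram, in micrometers. The radial profile is taken in 1-pixel
#' annuli; the first crossing of 0.5 going outward from the center is
#' located by linear sub-pixel interpolation and doubled (full width).
#'
#' @param acg Autocorrelogram from [autocorrelogram()], or a
#'   [height_profile()] (computed internally).
#' @param pitch Micrometers per pixel; taken from `acg`'s attribute when
#'   present.
#' @return Correlation length, micrometers.
#' @export
correlation_length <- function(acg, pitch = NULL) {
  if (inherits(acg, "height_profile")) {
    pitch <- acg$pixel_pitch
    acg <- autocorrelogram(acg)
  }
  if (is.null(pitch)) pitch <- attr(acg, "pitch")
  stopifnot(is.numeric(pitch), pitch > 0)
  ctr <- (dim(acg) + 1) / 2
  rp <- radial_profile(acg, ctr)
  rp <- rp[order(rp$r), ]
  below <- which(rp$value < 0.5)
  if (!length(below)) {
    stop(sprintf("autocorrelation never drops below 0.5 within the grid (lower bound %.1f um)",
                 2 * max(rp$r) * pitch))
  }
  k <- below[1]
  if (k == 1) return(0)
  r0 <- rp$r[k - 1]; v0 <- rp$value[k - 1]
  r1 <- rp$r[k]; v1 <- rp$value[k]
  r_half <- r0 + (v0 - 0.5) / (v0 - v1) * (r1 - r0)
  2 * r_half * pitch
}

#' Radially averaged spatial power spectrum and spectral centroid
#'
#' 2D power spectrum of the mean-subtracted, 2D-Hanning-windowed height
#' field, radially averaged into annular bins of one frequency step
#' (`1 / (min(n, m) * pitch)`), restricted to frequencies up to the Nyquist
#' limit `1 / (2 * pitch)`. The DC bin is excluded, which makes the summed
#' power (`sum(power * n)`) equal the population variance of the windowed
#' grid (Parseval). The spectral centroid is the power-weighted mean spatial
#' frequency of the radially averaged spectrum.
#'
#' @param profile A [height_profile()] or numeric matrix.
#' @param pitch Micrometers per pixel (for matrix input).
#' @param window Apply a 2D Hanning window (default `TRUE`).
#' @return List with `spectrum` (data.frame: `freq` 1/um, `power`, `n`),
#'   `centroid` (1/um) and `total_power` (um^2).
#' @export
spatial_spectrum <- function(profile, pitch = NULL, window = TRUE) {
  if (inherits(profile, "height_profile")) {
    pitch <- profile$pixel_pitch
    profile <- profile$heights
  }
  stopifnot(is.numeric(pitch), pitch > 0)
  h <- profile - mean(profile)
  nr <- nrow(h); nc <- ncol(h)
  if (window) {
    wr <- 0.5 * (1 - cos(2 * pi * (seq_len(nr) - 1) / (nr - 1)))
    wc <- 0.5 * (1 - cos(2 * pi * (seq_len(nc) - 1) / (nc - 1)))
    h <- h * outer(wr, wc)
  }
  h <- h - mean(h)
  FT <- fft(h)
  P <- Mod(FT)^2 / (nr * nc)^2
  fx <- (seq_len(nr) - 1) / nr; fx <- pmin(fx, 1 - fx) / pitch
  fy <- (seq_len(nc) - 1) / nc; fy <- pmin(fy, 1 - fy) / pitch
  fr <- sqrt(outer(fx^2, fy^2, `+`))
  df <- 1 / (min(nr, nc) * pitch)
  nyq <- 1 / (2 * pitch)
  keep <- fr <= nyq & fr > 0
  bin <- round(fr / df)
  pw <- tapply(P[keep], bin[keep], mean)
  cnt <- tapply(P[keep], bin[keep], length)
  spec <- data.frame(freq = as.numeric(names(pw)) * df,
                     power = as.numeric(pw), n = as.integer(cnt))
  spec <- spec[order(spec$freq), ]
  centroid <- sum(spec$freq * spec$power) / sum(spec$power)
  list(spectrum = spec, centroid = centroid,
       total_power = sum(P) - P[1, 1])
}

#' Summarize a cleaned surface
#'
#' Binned probability distributions of height, slope and angularity (each
#' sums to 1; samples whose differencing support touches an interpolated
#' pixel are omitted), the autocorrelogram correlation length, and the radial
#' spatial spectrum with its centroid.
#'
#' @param profile A cleaned [height_profile()].
#' @param bins Number of histogram bins per distribution (default 50).
#' @return An object of class `surface_summary`: list with elements
#'   `height_distribution`, `slope_distribution`, `angularity_distribution`
#'   (data.frames: `mid`, `p`), `correlation_length` (um),
#'   `spectral_centroid` (1/um), `spectrum`.
#' @export
surface_summary <- function(profile, bins = 50) {
  stopifnot(inherits(profile, "height_profile"))
  binned <- function(x) {
    br <- seq(min(x), max(x), length.out = bins + 1)
    if (br[1] == br[length(br)]) br <- br[1] + c(-0.5, 0.5)
    hh <- hist(x, breaks = br, plot = FALSE)
    data.frame(mid = hh$mids, p = hh$counts / sum(hh$counts))
  }
  hts <- profile$heights[!profile$artifact_mask]
  sl <- compute_slope(profile)
  an <- compute_angularity(profile)
  spec <- spatial_spectrum(profile)
  structure(list(
    height_distribution = binned(hts - mean(hts)),
    slope_distribution = binned(sl[attr(sl, "valid")]),
    angularity_distribution = binned(an[attr(an, "valid")]),
    correlation_length = correlation_length(profile),
    spectral_centroid = spec$centroid,
    spectrum = spec$spectrum),
    class = "surface_summary")
}

#' @export
print.surface_summary <- function(x, ...) {
  cat(sprintf("<surface_summary: correlation length %.1f um, spectral centroid %.4f 1/um>\n",
              x$correlation_length, x$spectral_centroid))
  invisible(x)
}

#' @importFrom graphics hist
NULL
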