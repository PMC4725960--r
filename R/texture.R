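#' Spectral band of the striation periodicity
#'
#' The band of spatial periods over which striation energy is integrated by
#' [fourier_i15()]. The default `[10, 20]` micrometers brackets the 15 um
#' period that gives the regularity index its name.
#'
#' @param period_min_um,period_max_um period bounds in micrometers,
#'   `0 < period_min_um < period_max_um`.
#' @return A list of class `spectral_band`.
#' @export
spectral_band <- function(period_min_um = 10, period_max_um = 20) {
  if (!is.numeric(period_min_um) || !is.numeric(period_max_um) ||
      period_min_um <= 0 || period_min_um >= period_max_um)
    stop("need 0 < period_min_um < period_max_um")
  structure(list(period_min_um = period_min_um,
                 period_max_um = period_max_um),
            class = "spectral_band")
}

#' Preprocess a frame for spectral analysis
#'
#' Centers the intensities, applies a separable 2-D Hann window to suppress
#' edge-discontinuity leakage, and re-centers so the windowed image has an
#' exactly zero mean (hence a zero DC bin). The pixel size is preserved.
#'
#' @param frame an [image_frame()].
#' @return An `image_frame` of windowed, zero-mean intensities (values may
#'   be negative; the frame is marked preprocessed and is not a physical
#'   image any more).
#' @export
preprocess <- function(frame) {
  stopifnot(is_image_frame(frame))
  m <- frame$intensities
  m <- m - mean(m)
  nr <- nrow(m); nc <- ncol(m)
  m <- m * (hann(nr) %o% hann(nc))
  m <- m - mean(m)
  out <- frame
  out$intensities <- m
  attr(out, "preprocessed") <- TRUE
  out
}

# periodic Hann window (DFT-symmetric)
hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# signed DFT frequencies in cycles/um for n samples at spacing d um
fft_freq <- function(n, d) {
  k <- seq_len(n) - 1
  ifelse(k <= n %/% 2, k, k - n) / (n * d)
}

#' Two-dimensional power spectrum in physical frequency units
#'
#' Squared magnitude of the 2-D discrete Fourier transform, scaled by
#' `1 / (rows * cols)` so that the total spectral energy equals the energy
#' of the (windowed) image, `sum(I^2)` (Parseval). Frequency axes follow
#' the standard DFT layout with the DC bin at the corner and are expressed
#' in cycles per micrometer via the frame's pixel size.
#'
#' @param frame an [image_frame()], normally output of [preprocess()]; a
#'   raw frame is preprocessed automatically.
#' @return A numeric matrix of class `power_spectrum` with attributes `fx`
#'   and `fy` (signed frequencies of the columns and rows, cycles/um).
#' @export
power_spectrum <- function(frame) {
  stopifnot(is_image_frame(frame))
  if (!isTRUE(attr(frame, "preprocessed"))) frame <- preprocess(frame)
  m <- frame$intensities
  ps <- Mod(fft(m))^2 / length(m)
  structure(ps,
            fx = fft_freq(ncol(m), frame$pixel_size_um),
            fy = fft_freq(nrow(m), frame$pixel_size_um),
            class = c("power_spectrum", "matrix"))
}

# radial frequency and in-plane angle (mod pi) of every spectrum bin
spectrum_coords <- function(ps) {
  fx <- attr(ps, "fx"); fy <- attr(ps, "fy")
  FX <- matrix(fx, nrow(ps), ncol(ps), byrow = TRUE)
  FY <- matrix(fy, nrow(ps), ncol(ps))
  list(FX = FX, FY = FY, r = sqrt(FX^2 + FY^2))
}

i15_score <- function(value, method, source_id, degenerate = FALSE) {
  structure(list(value = value, method = method, source_id = source_id,
                 degenerate = degenerate),
            class = "i15_score")
}

#' @export
print.i15_score <- function(x, ...) {
  cat(sprintf("I15 (%s) for '%s': %.4f%s\n", x$method, x$source_id,
              x$value, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
as.double.i15_score <- function(x, ...) x$value

#' Fourier regularity index I15
#'
#' Fraction of the image's non-DC spectral energy that falls in the
#' striation band: the annulus of spatial periods
#' `[period_min_um, period_max_um]` intersected with an angular sector of
#' half-width `sector_deg` about the dominant orientation. The dominant
#' orientation is the angle of the maximum-energy bin inside the annulus,
#' so the index tracks striations at any direction. A regular striated
#' texture concentrates nearly all its energy in one spectral line inside
#' the band, giving values near 1; an irregular reticular texture spreads
#' its energy over all frequencies and orientations, giving values near 0.
#'
#' A constant image carries no non-DC energy; its score is defined as 0 and
#' flagged degenerate.
#'
#' @param frame an [image_frame()].
#' @param band a [spectral_band()]; its shortest period must be resolvable,
#'   i.e. `period_min_um >= 2 * pixel_size_um`.
#' @param sector_deg angular sector half-width in degrees.
#' @return An `i15_score` with `value` in `[0, 1]` and `method "fourier"`.
#' @examples
#' fr <- generate_striated(striated_params(noise_sd = 0), seed = 1)
#' fourier_i15(fr)
#' @export
fourier_i15 <- function(frame, band = spectral_band(), sector_deg = 15) {
  stopifnot(is_image_frame(frame), inherits(band, "spectral_band"))
  if (band$period_min_um < 2 * frame$pixel_size_um)
    stop(sprintf(
      "band period_min_um (%g) is below the Nyquist period 2 * pixel_size_um (%g)",
      band$period_min_um, 2 * frame$pixel_size_um))
  ps <- power_spectrum(frame)
  co <- spectrum_coords(ps)
  nondc <- co$r > 0
  total <- sum(ps[nondc])
  if (total <= 1e-12 * length(ps))
    return(i15_score(0, "fourier", frame$source_id, degenerate = TRUE))
  annulus <- nondc & co$r >= 1 / band$period_max_um &
    co$r <= 1 / band$period_min_um
  if (!any(annulus))
    return(i15_score(0, "fourier", frame$source_id, degenerate = TRUE))
  peak <- which(annulus)[which.max(ps[annulus])]
  theta0 <- atan2(co$FY[peak], co$FX[peak]) %% pi
  ang <- atan2(co$FY, co$FX) %% pi
  d <- abs(ang - theta0)
  sector <- pmin(d, pi - d) <= sector_deg * pi / 180 + 1e-12
  i15_score(sum(ps[annulus & sector]) / total, "fourier", frame$source_id)
}

#' Second-order-moment regularity index I15
#'
#' Treats the normalized non-DC power spectrum as a probability mass over
#' signed frequency coordinates and computes its 2 x 2 second-order central
#' moment (covariance) matrix. With eigenvalues `lambda1 >= lambda2 >= 0`,
#' the index is the spectral anisotropy `1 - lambda2 / lambda1`: a pure
#' grating puts all mass on one line through the origin (rank-1 moments,
#' index 1), while an isotropic texture has equal eigenvalues (index 0).
#' Unlike [fourier_i15()] no band or orientation parameter is needed.
#'
#' @inheritParams fourier_i15
#' @return An `i15_score` with `value` in `[0, 1]` and `method "moments"`;
#'   a constant image scores 0 and is flagged degenerate.
#' @export
moment_i15 <- function(frame) {
  stopifnot(is_image_frame(frame))
  ps <- power_spectrum(frame)
  co <- spectrum_coords(ps)
  nondc <- co$r > 0
  total <- sum(ps[nondc])
  if (total <= 1e-12 * length(ps))
    return(i15_score(0, "moments", frame$source_id, degenerate = TRUE))
  p <- ps[nondc] / total
  fx <- co$FX[nondc]; fy <- co$FY[nondc]
  mx <- sum(p * fx); my <- sum(p * fy)
  cxx <- sum(p * (fx - mx)^2)
  cyy <- sum(p * (fy - my)^2)
  cxy <- sum(p * (fx - mx) * (fy - my))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE,
              only.values = TRUE)$values
  if (ev[1] <= 0)
    return(i15_score(0, "moments", frame$source_id, degenerate = TRUE))
  i15_score(1 - max(ev[2], 0) / ev[1], "moments", frame$source_id)
}

#' Score every image of a labeled set
#'
#' Applies one of the two I15 methods to each image of an [image_set()],
#' preserving order. Scoring is per-image (no cross-image state), so the
#' result is equivariant under permutation of the set.
#'
#' @param set an [image_set()] with at least one image.
#' @param method `"fourier"` or `"moments"`.
#' @param band a [spectral_band()], used by the Fourier method.
#' @param sector_deg angular sector half-width, used by the Fourier method.
#' @return A data frame with columns `source_id`, `method`, `i15`, `label`,
#'   `degenerate`, one row per image in input order.
#' @export
score_set <- function(set, method = c("fourier", "moments"),
                      band = spectral_band(), sector_deg = 15) {
  stopifnot(inherits(set, "image_set"))
  if (length(set) == 0L) stop("cannot score an empty image set")
  method <- match.arg(method)
  scores <- lapply(set$images, function(fr)
    switch(method,
           fourier = fourier_i15(fr, band = band, sector_deg = sector_deg),
           moments = moment_i15(fr)))
  data.frame(
    source_id = vapply(scores, `[[`, character(1), "source_id"),
    method = method,
    i15 = vapply(scores, `[[`, numeric(1), "value"),
    label = set$labels,
    degenerate = vapply(scores, `[[`, logical(1), "degenerate"),
    stringsAsFactors = FALSE)
}
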