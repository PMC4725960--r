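#' Parameters of the synthetic striated (AWM-like) texture
#'
#' Describes the regularly striated extracellular-space texture of atrial
#' working myocardium as a single oriented cosine modulation: rows of
#' aligned myocytes produce a quasi-periodic intensity pattern at a
#' characteristic spatial period. The model is
#' `baseline * (1 + contrast * cos(2*pi * x' / period + phi(row)))`, where
#' `x'` is the coordinate perpendicular to the striation direction and
#' `phi(row)` is Gaussian per-row phase jitter; the field is then blurred
#' with a Gaussian point-spread function, corrupted with additive Gaussian
#' noise, and clipped to `[0, 1]`.
#'
#' Defaults mimic fiber-optics confocal imaging with the topical-dye probe:
#' 1.8 um lateral resolution and a 169 x 120 um field of view (94 x 67
#' pixels). The 15 um default period is a plausible myocyte-row spacing
#' chosen for synthetic class separability, not a measured tissue value.
#'
#' @param period_um striation spatial period, micrometers; must exceed
#'   `2 * pixel_size_um` (Nyquist).
#' @param orientation_deg direction the striations run, degrees in
#'   `[0, 180)` from the image x-axis (0 = horizontal stripes, intensity
#'   modulated down the columns).
#' @param contrast amplitude of the periodic component relative to the mean
#'   intensity, in `(0, 1]` (0 allowed to produce a flat field).
#' @param jitter_sd_um standard deviation of per-row striation phase
#'   jitter, expressed in micrometers of displacement.
#' @param psf_fwhm_um full width at half maximum of the Gaussian blur
#'   emulating the optical point-spread function, micrometers.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param pixel_size_um micrometers per pixel.
#' @param shape_px integer `c(rows, cols)` image size in pixels.
#' @param baseline mean intensity of the field, in `(0, 1)`.
#' @return A validated list of class `striated_params`.
#' @seealso [generate_striated()], [reticular_params()]
#' @export
striated_params <- function(period_um = 15, orientation_deg = 0,
                            contrast = 0.6, jitter_sd_um = 1,
                            psf_fwhm_um = 1.8, noise_sd = 0.02,
                            pixel_size_um = 1.8, shape_px = c(67L, 94L),
                            baseline = 0.5) {
  p <- list(period_um = period_um, orientation_deg = orientation_deg %% 180,
            contrast = contrast, jitter_sd_um = jitter_sd_um,
            psf_fwhm_um = psf_fwhm_um, noise_sd = noise_sd,
            pixel_size_um = pixel_size_um,
            shape_px = as.integer(shape_px), baseline = baseline)
  check_positive(p, c("period_um", "pixel_size_um", "baseline"))
  check_nonneg(p, c("jitter_sd_um", "psf_fwhm_um", "noise_sd", "contrast"))
  if (p$contrast > 1) stop("'contrast' must be in [0, 1]")
  if (length(p$shape_px) != 2L || any(p$shape_px < 1L))
    stop("'shape_px' must be two positive integers (rows, cols)")
  if (p$period_um <= 2 * p$pixel_size_um)
    stop(sprintf(
      "period_um (%g) must exceed the Nyquist limit 2 * pixel_size_um (%g)",
      p$period_um, 2 * p$pixel_size_um))
  if (p$baseline >= 1) stop("'baseline' must be in (0, 1)")
  structure(p, class = "striated_params")
}

#' Parameters of the synthetic reticular (nodal-like) texture
#'
#' Describes the irregular, reticular extracellular-space texture of nodal
#' conduction tissue as an isotropic Gaussian random field: white noise
#' smoothed with a Gaussian filter, standardized, and scaled to the
#' requested contrast about the baseline. Its power spectrum decays
#' smoothly with no spectral line, in contrast to the striated model.
#'
#' `correlation_length_um` is defined spectrally: the Gaussian filter width
#' is chosen as `correlation_length_um / (4 * sqrt(pi))` so that the radial
#' centroid of the texture's power spectrum sits at
#' `1 / correlation_length_um` cycles per micrometer, i.e. the dominant
#' spatial scale of the mesh is the stated length.
#'
#' @inheritParams striated_params
#' @param correlation_length_um dominant spatial scale of the random
#'   texture, micrometers; positive.
#' @return A validated list of class `reticular_params`.
#' @seealso [generate_reticular()], [striated_params()]
#' @export
reticular_params <- function(correlation_length_um = 8, contrast = 0.6,
                             psf_fwhm_um = 1.8, noise_sd = 0.02,
                             pixel_size_um = 1.8, shape_px = c(67L, 94L),
                             baseline = 0.5) {
  p <- list(correlation_length_um = correlation_length_um,
            contrast = contrast, psf_fwhm_um = psf_fwhm_um,
            noise_sd = noise_sd, pixel_size_um = pixel_size_um,
            shape_px = as.integer(shape_px), baseline = baseline)
  check_positive(p, c("correlation_length_um", "pixel_size_um", "baseline"))
  check_nonneg(p, c("psf_fwhm_um", "noise_sd", "contrast"))
  if (p$contrast > 1) stop("'contrast' must be in [0, 1]")
  if (length(p$shape_px) != 2L || any(p$shape_px < 1L))
    stop("'shape_px' must be two positive integers (rows, cols)")
  if (p$baseline >= 1) stop("'baseline' must be in (0, 1)")
  structure(p, class = "reticular_params")
}

check_positive <- function(p, fields) {
  for (f in fields)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      stop("'", f, "' must be a single positive finite number")
  invisible(TRUE)
}

check_nonneg <- function(p, fields) {
  for (f in fields)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] < 0)
      stop("'", f, "' must be a single non-negative finite number")
  invisible(TRUE)
}

# FWHM -> Gaussian sigma in pixels; 0 disables the blur
psf_sigma_px <- function(psf_fwhm_um, pixel_size_um)
  psf_fwhm_um / (2 * sqrt(2 * log(2))) / pixel_size_um

gaussian_blur <- function(m, sigma_px) {
  if (sigma_px < 1e-3) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma_px))
}

#' Generate one synthetic striated image
#'
#' Draws a striated (AWM-like) frame from the model described in
#' [striated_params()]. The generator is a pure function of
#' `(params, seed)`: it neither reads nor perturbs the caller's random
#' number generator state, and the same arguments always return a
#' bit-identical image.
#'
#' @param params a [striated_params()] object.
#' @param seed integer seed.
#' @param source_id identifier stored in the frame.
#' @return An [image_frame()] with intensities in `[0, 1]`.
#' @examples
#' fr <- generate_striated(striated_params(), seed = 1)
#' @export
generate_striated <- function(params, seed, source_id = "striated") {
  stopifnot(inherits(params, "striated_params"))
  nr <- params$shape_px[1]; nc <- params$shape_px[2]
  px <- params$pixel_size_um
  img <- withr::with_seed(as.integer(seed), {
    # phase jitter: displacement jitter (um) converted to phase (rad)
    phi <- rnorm(nr, 0, 2 * pi * params$jitter_sd_um / params$period_um)
    x <- outer(rep(1, nr), (seq_len(nc) - 1) * px)
    y <- outer((seq_len(nr) - 1) * px, rep(1, nc))
    th <- params$orientation_deg * pi / 180
    xp <- -x * sin(th) + y * cos(th)   # coordinate across the striations
    field <- params$baseline *
      (1 + params$contrast * cos(2 * pi * xp / params$period_um +
                                 matrix(phi, nr, nc)))
    field <- gaussian_blur(field, psf_sigma_px(params$psf_fwhm_um, px))
    # partial periods and phase jitter drift the sample mean; recenter so
    # the noiseless field averages exactly to the configured baseline
    field <- field - mean(field) + params$baseline
    if (params$noise_sd > 0)
      field <- field + matrix(rnorm(nr * nc, 0, params$noise_sd), nr, nc)
    field
  })
  image_frame(pmin(pmax(img, 0), 1), px, source_id)
}

#' Generate one synthetic reticular image
#'
#' Draws a reticular (nodal-like) frame from the isotropic Gaussian random
#' field model described in [reticular_params()]: smoothed white noise,
#' standardized and scaled so that the 3-sigma excursion of the texture
#' equals `contrast * baseline`, then PSF-blurred, noise-corrupted and
#' clipped to `[0, 1]`. Pure function of `(params, seed)`.
#'
#' @param params a [reticular_params()] object.
#' @inheritParams generate_striated
#' @return An [image_frame()] with intensities in `[0, 1]`.
#' @export
generate_reticular <- function(params, seed, source_id = "reticular") {
  stopifnot(inherits(params, "reticular_params"))
  nr <- params$shape_px[1]; nc <- params$shape_px[2]
  px <- params$pixel_size_um
  img <- withr::with_seed(as.integer(seed), {
    z <- matrix(rnorm(nr * nc), nr, nc)
    if (params$contrast > 0) {
      sigma_um <- params$correlation_length_um / (4 * sqrt(pi))
      z <- gaussian_blur(z, sigma_um / px)
      z <- (z - mean(z)) / sd(z)
      field <- params$baseline * (1 + params$contrast * z / 3)
    } else {
      field <- matrix(params$baseline, nr, nc)
    }
    field <- gaussian_blur(field, psf_sigma_px(params$psf_fwhm_um, px))
    field <- field - mean(field) + params$baseline
    if (params$noise_sd > 0)
      field <- field + matrix(rnorm(nr * nc, 0, params$noise_sd), nr, nc)
    field
  })
  image_frame(pmin(pmax(img, 0), 1), px, source_id)
}

#' Derive the per-image sub-seed from a master seed
#'
#' Portable linear congruential mix, `(69069 * seed + 1234567 * index +
#' 99991) mod 2147483647`, exact in double-precision arithmetic. Because
#' the sub-seed depends only on the master seed and the image's position,
#' regenerating any single image independently of the others reproduces it
#' bit-for-bit.
#'
#' @param master_seed integer master seed.
#' @param index 1-based image index within the dataset.
#' @return An integer sub-seed in `[0, 2^31 - 2]`.
#' @export
derive_subseed <- function(master_seed, index) {
  s <- as.double(master_seed) %% 2147483647
  as.integer((69069 * s + 1234567 * as.double(index) + 99991) %% 2147483647)
}

#' Generate a labeled synthetic dataset of both tissue classes
#'
#' Produces `n_awm` striated frames labeled `"AWM"` followed by `n_nodal`
#' reticular frames labeled `"NODAL"`. Each image gets its own sub-seed via
#' [derive_subseed()] (AWM images use indices `1..n_awm`, nodal images
#' continue at `n_awm + 1`), so the content of an image does not depend on
#' how many others are generated alongside it in either class block.
#'
#' @param n_awm,n_nodal non-negative image counts per class; the defaults
#'   give the 81 + 81 evaluation-set size used throughout.
#' @param striated a [striated_params()] object.
#' @param reticular a [reticular_params()] object.
#' @param seed integer master seed.
#' @return An [image_set()] of `n_awm + n_nodal` frames.
#' @examples
#' ds <- generate_dataset(3, 3, seed = 7)
#' table(ds$labels)
#' @export
generate_dataset <- function(n_awm = 81, n_nodal = 81,
                             striated = striated_params(),
                             reticular = reticular_params(),
                             seed = 1L) {
  if (n_awm < 0 || n_nodal < 0) stop("image counts must be non-negative")
  n_awm <- as.integer(n_awm); n_nodal <- as.integer(n_nodal)
  imgs <- vector("list", n_awm + n_nodal)
  for (i in seq_len(n_awm))
    imgs[[i]] <- generate_striated(striated, derive_subseed(seed, i),
                                   source_id = sprintf("awm_%04d", i))
  for (j in seq_len(n_nodal))
    imgs[[n_awm + j]] <- generate_reticular(
      reticular, derive_subseed(seed, n_awm + j),
      source_id = sprintf("nodal_%04d", j))
  image_set(imgs, rep(c("AWM", "NODAL"), c(n_awm, n_nodal)),
            seed = as.integer(seed))
}

#' Imaging presets matching the acquisition configurations
#'
#' Returns striated and reticular parameter pairs at the pixel size and
#' field of view of the three imaging configurations: `fcm_topical`
#' (1.8 um/px, 169 x 120 um), `fcm_carrier` (1.4 um/px, 186 x 130 um) and
#' `ccm` (conventional confocal, here 0.7 um/px over 180 x 180 um).
#'
#' @param preset one of `"fcm_topical"`, `"fcm_carrier"`, `"ccm"`.
#' @return A list with elements `striated` and `reticular`.
#' @export
imaging_preset <- function(preset = c("fcm_topical", "fcm_carrier", "ccm")) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    fcm_topical = list(px = 1.8, fov = c(120, 169), res = 1.8),
    fcm_carrier = list(px = 1.4, fov = c(130, 186), res = 1.4),
    ccm         = list(px = 0.7, fov = c(180, 180), res = 0.7))
  shape <- as.integer(round(cfg$fov / cfg$px))
  list(
    striated = striated_params(pixel_size_um = cfg$px, shape_px = shape,
                               psf_fwhm_um = cfg$res),
    reticular = reticular_params(pixel_size_um = cfg$px, shape_px = shape,
                                 psf_fwhm_um = cfg$res))
}
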