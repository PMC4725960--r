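test_that("generators are pure, seeded functions of (params, seed)", {
  sp <- small_striated(); rp <- small_reticular()
  a <- generate_striated(sp, seed = 11)
  b <- generate_striated(sp, seed = 11)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities,
                         generate_striated(sp, seed = 12)$intensities))
  expect_identical(generate_reticular(rp, seed = 11)$intensities,
                   generate_reticular(rp, seed = 11)$intensities)
  # the caller's RNG stream is untouched
  set.seed(99); before <- .Random.seed
  invisible(generate_striated(sp, seed = 5))
  invisible(generate_reticular(rp, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("zero contrast and zero noise give a constant image", {
  fs <- generate_striated(small_striated(contrast = 0, noise_sd = 0), seed = 1)
  expect_equal(diff(range(fs$intensities)), 0)
  expect_equal(mean(fs$intensities), 0.5)
  fr <- generate_reticular(small_reticular(contrast = 0, noise_sd = 0), seed = 1)
  expect_equal(diff(range(fr$intensities)), 0)
})

test_that("mean intensity stays within 1% of the configured baseline", {
  for (seed in 1:5) {
    fs <- generate_striated(striated_params(), seed = seed)
    expect_lt(abs(mean(fs$intensities) - 0.5), 0.005)
    fr <- generate_reticular(reticular_params(), seed = seed)
    expect_lt(abs(mean(fr$intensities) - 0.5), 0.005)
  }
})

test_that("striation period shows up as the autocorrelation peak lag", {
  # period 15 um at 1.8 um/px = 8.33 px; horizontal striations modulate
  # down the columns, so the column autocorrelation peaks at the nearest
  # integer lag
  sp <- striated_params(period_um = 15, jitter_sd_um = 0, noise_sd = 0,
                        psf_fwhm_um = 0, orientation_deg = 0)
  fr <- generate_striated(sp, seed = 3)
  lag_px <- 15 / sp$pixel_size_um
  for (j in c(1, 40, 94)) {
    v <- fr$intensities[, j]
    ac <- stats::acf(v - mean(v), lag.max = 12, plot = FALSE,
                     demean = FALSE)$acf[-1]
    expect_equal(which.max(ac), round(lag_px))
  }
})

test_that("striated spectrum peaks at 1/period along the orientation", {
  sp <- striated_params(period_um = 15, jitter_sd_um = 0, noise_sd = 0,
                        psf_fwhm_um = 0, orientation_deg = 0,
                        shape_px = c(96L, 96L))
  ps <- power_spectrum(generate_striated(sp, seed = 1))
  fx <- attr(ps, "fx"); fy <- attr(ps, "fy")
  k <- arrayInd(which.max(ps), dim(ps))
  # horizontal stripes: wave vector along fy, magnitude 1/15 cycles/um
  expect_equal(fx[k[2]], 0)
  expect_equal(abs(fy[k[1]]), 1 / 15, tolerance = 0.07)
})

test_that("reticular spectral centroid matches 1/correlation_length", {
  rp <- reticular_params(correlation_length_um = 8, noise_sd = 0,
                         psf_fwhm_um = 0.3)
  cents <- vapply(1:4, function(seed) {
    ps <- power_spectrum(generate_reticular(rp, seed = seed))
    fx <- attr(ps, "fx"); fy <- attr(ps, "fy")
    r <- sqrt(outer(fy^2, fx^2, "+"))
    sum(ps[r > 0] * r[r > 0]) / sum(ps[r > 0])
  }, numeric(1))
  expect_true(all(abs(cents - 1 / 8) / (1 / 8) < 0.25))
})

test_that("reticular radial spectrum has no isolated narrow-band peak", {
  rp <- reticular_params(noise_sd = 0)
  ps <- power_spectrum(generate_reticular(rp, seed = 2))
  fx <- attr(ps, "fx"); fy <- attr(ps, "fy")
  r <- sqrt(outer(fy^2, fx^2, "+"))
  edges <- seq(0, max(abs(fx)), length.out = 14)
  prof <- vapply(seq_len(length(edges) - 1), function(i)
    mean(ps[r > edges[i] & r <= edges[i + 1]]), numeric(1))
  prof <- prof[is.finite(prof)]
  # interior bins never jut out above their neighbours' mean; a striated
  # image violates this decisively at the spectral line
  prominence <- function(p) {
    n <- length(p)
    max(p[2:(n - 1)] / ((p[1:(n - 2)] + p[3:n]) / 2))
  }
  expect_lt(prominence(prof), 2.5)
  pss <- power_spectrum(generate_striated(
    striated_params(jitter_sd_um = 0, noise_sd = 0), seed = 2))
  profs <- vapply(seq_len(length(edges) - 1), function(i)
    mean(pss[r > edges[i] & r <= edges[i + 1]]), numeric(1))
  expect_gt(prominence(profs), 2.5)
})

test_that("parameter invariants are enforced", {
  expect_error(striated_params(period_um = 3, pixel_size_um = 1.8), "Nyquist")
  expect_error(striated_params(contrast = 1.5), "contrast")
  expect_error(reticular_params(correlation_length_um = 0), "positive")
  expect_error(reticular_params(correlation_length_um = -4), "positive")
  expect_error(striated_params(pixel_size_um = 0), "positive")
})

test_that("generate_dataset sizes, labels and emptiness behave", {
  expect_length(generate_dataset(0, 0, seed = 1), 0)
  ds <- generate_dataset(5, 7, small_striated(), small_reticular(), seed = 9)
  expect_length(ds, 12)
  expect_identical(ds$labels, rep(c("AWM", "NODAL"), c(5, 7)))
  expect_identical(table(ds$labels)[["AWM"]], 5L)
})

test_that("per-image sub-seeding is independent of set composition", {
  sp <- small_striated(); rp <- small_reticular()
  ds <- generate_dataset(4, 3, sp, rp, seed = 77)
  # each image regenerated in isolation from its derived sub-seed
  for (i in 1:4)
    expect_identical(ds$images[[i]]$intensities,
                     generate_striated(sp, derive_subseed(77, i))$intensities)
  for (j in 1:3)
    expect_identical(ds$images[[4 + j]]$intensities,
                     generate_reticular(rp, derive_subseed(77, 4 + j))$intensities)
  # the AWM block is unaffected by how many nodal images follow it
  ds2 <- generate_dataset(4, 0, sp, rp, seed = 77)
  for (i in 1:4)
    expect_identical(ds2$images[[i]]$intensities, ds$images[[i]]$intensities)
})

test_that("increasing jitter or noise strictly degrades mean fourier I15", {
  mean_i15 <- function(p) mean(vapply(1:10, function(s)
    fourier_i15(generate_striated(p, seed = s))$value, numeric(1)))
  jit <- vapply(c(0.5, 1.5, 3), function(j)
    mean_i15(striated_params(jitter_sd_um = j)), numeric(1))
  expect_true(all(diff(jit) < 0))
  noi <- vapply(c(0.02, 0.08, 0.2), function(ns)
    mean_i15(striated_params(noise_sd = ns)), numeric(1))
  expect_true(all(diff(noi) < 0))
})

test_that("imaging presets reproduce the acquisition geometries", {
  top <- imaging_preset("fcm_topical")
  expect_equal(top$striated$pixel_size_um, 1.8)
  expect_equal(top$striated$shape_px, c(67L, 94L))
  car <- imaging_preset("fcm_carrier")
  expect_equal(car$striated$pixel_size_um, 1.4)
  expect_equal(car$striated$shape_px, c(93L, 133L))
})
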