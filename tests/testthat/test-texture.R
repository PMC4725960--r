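test_that("preprocess centers, windows and never reintroduces a DC term", {
  const <- image_frame(matrix(0.7, 20, 20), 1.8)
  expect_true(all(preprocess(const)$intensities == 0))
  for (seed in 1:5) {
    fr <- random_frame(seed, n = 20)
    out <- preprocess(fr)
    expect_lt(abs(sum(out$intensities)), 1e-6 * length(out$intensities))
    expect_equal(out$pixel_size_um, fr$pixel_size_um)
    # re-windowing a windowed zero-mean image only rescales amplitudes
    again <- preprocess(out)
    expect_lt(abs(sum(again$intensities)), 1e-9 * length(out$intensities))
  }
})

test_that("frames below 16x16 are rejected", {
  expect_error(image_frame(matrix(1, 8, 8), 1.8), "16 x 16")
  expect_error(image_frame(matrix(-1, 20, 20), 1.8), "non-negative")
})

test_that("power spectrum satisfies Parseval and kills the DC bin", {
  for (seed in 1:5) {
    pre <- preprocess(random_frame(seed, n = 24))
    ps <- power_spectrum(pre)
    expect_equal(sum(ps), sum(pre$intensities^2), tolerance = 1e-6)
    expect_lt(ps[1, 1], 1e-12 * sum(ps))
  }
})

test_that("a pure cosine grating concentrates energy in its conjugate bins", {
  n <- 32; px <- 1
  # period 8 um along x -> bins at fx = +/- 1/8, fy = 0; skip the window
  # to make the concentration exact
  m <- 0.5 + 0.25 * cos(2 * pi * outer(rep(1, n), 0:(n - 1)) / 8)
  fr <- image_frame(m - mean(m) + 0.5, px)
  pre <- fr; pre$intensities <- pre$intensities - mean(pre$intensities)
  attr(pre, "preprocessed") <- TRUE
  ps <- power_spectrum(pre)
  fx <- attr(ps, "fx"); fy <- attr(ps, "fy")
  hit <- outer(fy == 0, abs(abs(fx) - 1 / 8) < 1e-12, FUN = "&")
  expect_equal(sum(ps[hit]) / sum(ps), 1, tolerance = 1e-9)
})

test_that("power spectrum matches the naive O(N^4) DFT oracle", {
  for (seed in 1:3) {
    pre <- preprocess(random_frame(seed, n = 16))
    expect_equal(unclass(power_spectrum(pre))[],
                 naive_power_spectrum(pre$intensities),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("fourier I15 handles degenerate and ideal inputs", {
  sc <- fourier_i15(image_frame(matrix(0.3, 20, 20), 1.8))
  expect_equal(sc$value, 0)
  expect_true(sc$degenerate)
  # noiseless 15 um grating: essentially all energy in band and sector
  fr <- generate_striated(
    striated_params(period_um = 15, jitter_sd_um = 0, noise_sd = 0,
                    psf_fwhm_um = 0), seed = 1)
  expect_equal(fourier_i15(fr)$value, 1, tolerance = 0.01)
  # band entirely below the Nyquist period is rejected
  expect_error(fourier_i15(fr, spectral_band(2, 5)), "Nyquist")
})

test_that("fourier I15 equals the scalar-loop band-energy oracle", {
  for (seed in 1:5) {
    fr <- random_frame(seed, n = 16, px = 2)
    got <- fourier_i15(fr, spectral_band(6, 14), sector_deg = 20)$value
    want <- naive_band_fraction(power_spectrum(fr), 6, 14, 20)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("moment I15 handles isotropic, grating and degenerate inputs", {
  sc <- moment_i15(image_frame(matrix(0.3, 20, 20), 1.8))
  expect_equal(sc$value, 0)
  expect_true(sc$degenerate)
  # equal-amplitude crossed gratings: spectrum mass at (+/-f, 0), (0, +/-f)
  # has equal second moments in x and y -> isotropic covariance, index 0
  n <- 48
  g <- outer(0:(n - 1), rep(1, n)) ; h <- t(g)
  m <- 0.5 + 0.2 * cos(2 * pi * g / 8) + 0.2 * cos(2 * pi * h / 8)
  cross <- image_frame(pmin(pmax(m, 0), 1), 1)
  expect_lt(moment_i15(cross)$value, 0.05)
  # a single grating is rank-1: index ~ 1
  fr <- generate_striated(
    striated_params(period_um = 15, jitter_sd_um = 0, noise_sd = 0,
                    psf_fwhm_um = 0), seed = 1)
  expect_gt(moment_i15(fr)$value, 0.99)
})

test_that("moment I15 equals the scalar-loop moment oracle", {
  for (seed in 1:5) {
    fr <- random_frame(seed, n = 16)
    expect_equal(moment_i15(fr)$value,
                 naive_moment_index(power_spectrum(fr)),
                 tolerance = 1e-9)
  }
})

test_that("both scores are invariant to intensity scaling and offset", {
  for (seed in 1:3) {
    fr <- random_frame(seed, n = 24)
    scaled <- fr; scaled$intensities <- 0.37 * fr$intensities
    shifted <- fr; shifted$intensities <- fr$intensities + 0.21
    for (f in list(fourier_i15, moment_i15)) {
      expect_equal(f(scaled)$value, f(fr)$value, tolerance = 1e-12)
      expect_equal(f(shifted)$value, f(fr)$value, tolerance = 1e-12)
    }
  }
})

test_that("fourier I15 is invariant under 90-degree rotation", {
  sp <- striated_params(shape_px = c(64L, 64L), orientation_deg = 0)
  fr <- generate_striated(sp, seed = 4)
  n <- nrow(fr$intensities)
  # lattice rotation by 90 degrees (transpose + reflection about the DFT
  # origin), an exact permutation of the spectrum on a square frame
  rot <- fr
  rot$intensities <- t(fr$intensities)[, c(1, n:2)]
  expect_equal(fourier_i15(rot)$value, fourier_i15(fr)$value,
               tolerance = 1e-9)
  # plain matrix rotation shifts the window by one pixel; still invariant
  # up to that discretization
  rot2 <- fr
  rot2$intensities <- t(fr$intensities)[, n:1]
  expect_equal(fourier_i15(rot2)$value, fourier_i15(fr)$value,
               tolerance = 0.01)
})

test_that("moment I15 is rotation-invariant up to discretization", {
  vals <- vapply(c(0, 30, 45, 60, 120), function(th)
    moment_i15(generate_striated(
      striated_params(orientation_deg = th, jitter_sd_um = 0,
                      noise_sd = 0, shape_px = c(96L, 96L)),
      seed = 2))$value, numeric(1))
  expect_lt(diff(range(vals)), 0.05)
})

test_that("score_set preserves order, purity and rejects empty sets", {
  ds <- generate_dataset(3, 3, small_striated(), small_reticular(), seed = 5)
  sc <- score_set(ds, "fourier")
  expect_equal(nrow(sc), 6)
  expect_identical(sc$label, ds$labels)
  one <- score_set(ds[2], "moments")
  expect_equal(nrow(one), 1)
  expect_equal(one$i15, score_set(ds, "moments")$i15[2])
  perm <- c(4, 1, 6, 2, 3, 5)
  expect_equal(score_set(ds[perm], "fourier")$i15, sc$i15[perm])
  expect_error(score_set(generate_dataset(0, 0, seed = 1)), "empty")
})
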