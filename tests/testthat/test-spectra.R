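# spectra: builders, Wiener-Khintchine transforms, convolution

test_that("theta spectrum peaks at its center frequency and integrates to its variance", {
  for (fc in c(6, 15)) {
    s <- make_theta_spectrum(fc, 2, 1, TEST_DELTA, TEST_NGRID)
    pos <- s$freqs > 0
    expect_equal(s$freqs[pos][which.max(s$power[pos])], fc,
                 tolerance = 1.5 * diff(s$freqs)[1])
    expect_equal(spectrum_variance(s), 1, tolerance = 1e-6)
  }
  s3 <- make_theta_spectrum(6, 2, 2.5, TEST_DELTA, TEST_NGRID)
  expect_equal(spectrum_variance(s3), 2.5, tolerance = 1e-6)
  expect_error(make_theta_spectrum(499.5, 2, 1, TEST_DELTA, TEST_NGRID), "Nyquist")
  expect_error(make_theta_spectrum(6, -1, 1, TEST_DELTA, TEST_NGRID))
})

test_that("noise spectrum follows 1/f^alpha above the floor", {
  for (alpha in c(1, 2)) {
    s <- make_noise_spectrum(alpha, 1, 0.5, TEST_DELTA, TEST_NGRID)
    sel <- s$freqs >= 2 & s$freqs <= 100
    fit <- stats::lm(log10(s$power[sel]) ~ log10(s$freqs[sel]))
    expect_equal(unname(stats::coef(fit)[2]), -alpha, tolerance = 1e-6)
    # power-law scaling between two grid frequencies
    i1 <- which.min(abs(s$freqs - 10)); i2 <- which.min(abs(s$freqs - 20))
    expect_equal(s$power[i1] / s$power[i2],
                 (s$freqs[i2] / s$freqs[i1])^alpha, tolerance = 1e-9)
    expect_equal(spectrum_variance(s), 1, tolerance = 1e-6)
  }
  expect_error(make_noise_spectrum(0, 1, 0.5, TEST_DELTA, TEST_NGRID), "alpha")
  expect_error(make_noise_spectrum(2, 1, -0.1, TEST_DELTA, TEST_NGRID), "floor_f")
})

test_that("band spectrum has the right support, centroid, and boxcar density", {
  s <- make_band_spectrum(100, 140, 1, 4, TEST_DELTA, TEST_NGRID)
  pos <- s$freqs > 0
  f <- s$freqs[pos]; p <- s$power[pos]
  expect_equal(sum(f * p) / sum(p), 120, tolerance = 0.5)
  expect_lt(max(p[f < 95 | f > 145]), 1e-12 * max(p))
  # exact boxcar: two-sided density value at band center
  s0 <- make_band_spectrum(100, 140, 1, 0, TEST_DELTA, TEST_NGRID)
  at <- s0$power[which.min(abs(s0$freqs - 120))]
  # r0 = delta * integral => density on the band is variance/(delta*2*width)
  expect_equal(at, 1 / (TEST_DELTA * 2 * 40), tolerance = 0.02)
  expect_error(make_band_spectrum(100, 600, 1, 4, TEST_DELTA, TEST_NGRID), "Nyquist")
  expect_error(make_band_spectrum(140, 100, 1, 4, TEST_DELTA, TEST_NGRID))
})

test_that("spectrum_to_acv equals brute-force quadrature and preserves variance", {
  specs <- list(make_theta_spectrum(6, 2, 1, TEST_DELTA, TEST_NGRID),
                make_band_spectrum(100, 140, 2, 4, TEST_DELTA, TEST_NGRID),
                make_noise_spectrum(2, 0.5, 0.5, TEST_DELTA, TEST_NGRID))
  for (s in specs) {
    a <- spectrum_to_acv(s, 50)
    expect_equal(a$values[1], spectrum_variance(s), tolerance = 1e-10)
    expect_equal(a$values, oracle_quadrature_acv(s, 0:50), tolerance = 1e-10)
  }
  expect_error(spectrum_to_acv(specs[[1]], TEST_NGRID), "resolution")
})

test_that("boxcar band acv is a 120 Hz-modulated envelope with first zero near 1/40 s", {
  s <- make_band_spectrum(100, 140, 1, 0, TEST_DELTA, 8192L)
  a <- spectrum_to_acv(s, 60)
  # envelope of r_tau: |r| at multiples of the 120 Hz carrier period
  env <- abs(a$values)
  # sinc envelope of a 40 Hz-wide band first vanishes at tau = 1/40 s = lag 25
  expect_lt(min(env[20:30]) / env[1], 0.08)
  expect_gt(env[13] / env[1], 0.5)  # still large at half that lag
})

test_that("white and single-tone autocovariances transform as expected", {
  # white: r = sigma^2 delta_{tau,0} -> flat spectrum sigma^2 (density units)
  a <- acv_seq(c(2, rep(0, 30)), TEST_DELTA)
  s <- acv_to_spectrum(a, TEST_NGRID)
  expect_lt(diff(range(s$power)), 1e-12)
  expect_equal(spectrum_variance(s), 2, tolerance = 1e-6)
  # tone: r = cos(2 pi f0 tau delta) -> peaks at +-f0
  f0 <- 40
  tone <- acv_seq(cos(2 * pi * f0 * (0:400) * TEST_DELTA), TEST_DELTA)
  # a hard-truncated cosine has real negative sidelobes: clipping is warned
  expect_warning(st <- acv_to_spectrum(tone, TEST_NGRID), "clipping")
  pos <- st$freqs > 0
  expect_equal(st$freqs[pos][which.max(st$power[pos])], f0,
               tolerance = 2 * diff(st$freqs)[1])
})

test_that("spectrum <-> acv round trips agree on band interiors", {
  s <- make_theta_spectrum(6, 2, 1, TEST_DELTA, TEST_NGRID)
  s2 <- acv_to_spectrum(spectrum_to_acv(s, TEST_NGRID %/% 2), TEST_NGRID)
  interior <- s$freqs > 3 & s$freqs < 9
  expect_equal(s2$power[interior], s$power[interior],
               tolerance = 1e-6 * max(s$power))
})

test_that("convolution obeys the lag-product duality and the impulse identity", {
  pairs <- list(
    list(make_theta_spectrum(6, 2, 1, TEST_DELTA, TEST_NGRID),
         make_band_spectrum(100, 140, 1, 4, TEST_DELTA, TEST_NGRID)),
    list(make_theta_spectrum(15, 2, 0.5, TEST_DELTA, TEST_NGRID),
         make_band_spectrum(30, 50, 2, 4, TEST_DELTA, TEST_NGRID)),
    list(make_noise_spectrum(2, 1, 0.5, TEST_DELTA, TEST_NGRID),
         make_theta_spectrum(6, 2, 1, TEST_DELTA, TEST_NGRID)))
  for (pr in pairs) {
    cv <- convolve_spectra(pr[[1]], pr[[2]])
    la <- spectrum_to_acv(pr[[1]], TEST_NGRID %/% 2)
    lb <- spectrum_to_acv(pr[[2]], TEST_NGRID %/% 2)
    dual <- acv_to_spectrum(acv_seq(la$values * lb$values, TEST_DELTA), TEST_NGRID)
    expect_equal(cv$power, dual$power, tolerance = 1e-6 * max(cv$power))
    expect_equal(spectrum_variance(cv),
                 spectrum_variance(pr[[1]]) * spectrum_variance(pr[[2]]),
                 tolerance = 1e-6)
  }
  # unit-mass impulse at f = 0 is the identity element
  s <- make_band_spectrum(100, 140, 1, 4, TEST_DELTA, TEST_NGRID)
  df <- s$freqs[2] - s$freqs[1]
  imp_power <- numeric(length(s$freqs))
  imp_power[which.min(abs(s$freqs))] <- 1 / (TEST_DELTA * df)  # unit variance
  imp <- spectrum_spec(s$freqs, imp_power, TEST_DELTA)
  out <- convolve_spectra(s, imp)
  expect_equal(out$power, s$power, tolerance = 1e-6 * max(s$power))
  # mismatched grids rejected
  other <- make_theta_spectrum(6, 2, 1, TEST_DELTA, 1024L)
  expect_error(convolve_spectra(s, other), "grid")
})

test_that("all builder spectra are even and nonnegative", {
  specs <- list(make_theta_spectrum(6, 2, 1, TEST_DELTA, TEST_NGRID),
                make_theta_spectrum(15, 2, 3, TEST_DELTA, TEST_NGRID),
                make_noise_spectrum(2, 1, 0.5, TEST_DELTA, TEST_NGRID),
                make_band_spectrum(30, 50, 1, 4, TEST_DELTA, TEST_NGRID),
                make_band_spectrum(100, 140, 1, 0, TEST_DELTA, TEST_NGRID))
  for (s in specs) {
    expect_true(all(s$power >= 0))
    expect_equal(s$power, rev(s$power), tolerance = 1e-9)
    # Wiener-Khintchine consistency: r_0 == requested variance
    expect_equal(spectrum_to_acv(s, 0)$values[1], spectrum_variance(s),
                 tolerance = 1e-6)
  }
})

test_that("spectrum and acv tables round-trip through disk", {
  s <- make_theta_spectrum(6, 2, 1, TEST_DELTA, 512L)
  stem <- file.path(withr::local_tempdir(), "theta")
  write_spectrum_table(s, stem)
  tab <- utils::read.csv(paste0(stem, ".csv"))
  expect_equal(tab$power, s$power)
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(meta$label, "theta")
  expect_equal(meta$delta_s, TEST_DELTA)
})
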