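# coupling: gates, Isserlis moment calculus, gamma second-order theory

test_that("coupling_spec defaults carry the K = 4 gate weights", {
  cp <- coupling_spec("pulsatile")
  expect_equal(cp$K, 4L)
  expect_equal(cp$weights, c(0.4783, 0.2625, 0.0933, 0.0292, 0.0058))
  expect_equal(coupling_spec("biphasic", f_theta = 6)$harmonic_spacing, 12)
  expect_error(coupling_spec("pulsatile", weights = numeric(0)))
})

test_that("gates behave as specified on simple theta paths", {
  n <- 100
  th <- sample_path(sin(2 * pi * 6 * (0:(n - 1)) * TEST_DELTA), TEST_DELTA,
                    variance = 1)
  # sinusoidal, tau = 0: identity
  e <- envelope(th, coupling_spec("sinusoidal"))
  expect_equal(e$values, th$values)
  # pulsatile on theta == 0: constant w_0
  th0 <- sample_path(rep(0, n), TEST_DELTA, variance = 1)
  e0 <- envelope(th0, coupling_spec("pulsatile"), theta_var = 1)
  expect_equal(e0$values, rep(0.4783, n))
  # biphasic gate is even in theta
  cb <- coupling_spec("biphasic")
  neg <- sample_path(-th$values, TEST_DELTA, variance = 1)
  expect_equal(envelope(th, cb, theta_var = 1)$values,
               envelope(neg, cb, theta_var = 1)$values)
  # lag boundary: tau = 3 marks the last 3 samples invalid
  e3 <- envelope(th, coupling_spec("sinusoidal", tau = 3L))
  expect_true(all(is.na(e3$values[(n - 2):n])))
  expect_equal(e3$values[1:(n - 3)], th$values[4:n])
  expect_error(envelope(th, coupling_spec("sinusoidal", tau = 200L)), "tau")
})

test_that("make_gamma multiplies the gate with x and checks alignment", {
  n <- 128
  th <- sample_path(cos(2 * pi * 6 * (0:(n - 1)) * TEST_DELTA), TEST_DELTA,
                    variance = 1)
  zero_x <- sample_path(rep(0, n), TEST_DELTA)
  expect_equal(make_gamma(th, zero_x, coupling_spec("pulsatile"))$values,
               rep(0, n))
  one_x <- sample_path(rep(1, n), TEST_DELTA)
  expect_equal(make_gamma(th, one_x, coupling_spec("sinusoidal"))$values,
               th$values)
  short_x <- sample_path(rep(1, n - 1), TEST_DELTA)
  expect_error(make_gamma(th, short_x, coupling_spec("sinusoidal")), "length")
})

test_that("pulsatile gate pulses recur at the theta period", {
  # ~167 ms between envelope maxima for a 6 Hz rhythm
  n <- 20000
  s_th <- make_theta_spectrum(6, 2, 1, TEST_DELTA, 8192L)
  th <- circulant_draw(spectrum_to_acv(s_th, 2000), n, 77)
  e <- envelope(th, coupling_spec("pulsatile"), theta_var = 1)$values
  # peak-interval histogram of the gate
  is_pk <- which(diff(sign(diff(e))) == -2) + 1L
  is_pk <- is_pk[e[is_pk] > stats::quantile(e, 0.8)]
  gaps <- diff(is_pk) * TEST_DELTA
  gaps <- gaps[gaps > 0.05]          # ignore jitter within one pulse
  expect_equal(stats::median(gaps), 1 / 6, tolerance = 0.15)
})

test_that("Wick closed form matches brute-force pairing enumeration to j+k = 8", {
  r0 <- 1.3; rt <- -0.7
  for (j in 0:8) for (k in 0:(8 - j)) {
    expect_equal(gaussian_cross_moment(j, k, r0, rt),
                 oracle_cross_moment(j, k, r0, rt),
                 tolerance = 1e-12,
                 label = sprintf("moment j=%d k=%d", j, k))
  }
  expect_identical(gaussian_cross_moment(1, 2, 1, 0.3), 0)
  expect_equal(gaussian_cross_moment(1, 1, 2, 0.5), 0.5)
  expect_equal(gaussian_cross_moment(2, 0, 2, 0.5), 2)
  expect_equal(gaussian_cross_moment(4, 0, 2, 0.5), 3 * 4)
  expect_equal(gaussian_cross_moment(2, 2, 2, 0.5), 4 + 2 * 0.25)
  expect_error(gaussian_cross_moment(-1, 2, 1, 0), "nonnegative")
  expect_error(gaussian_cross_moment(2, 2, 1, 1.5), "exceed")
})

test_that("envelope theory reduces correctly and matches Monte Carlo", {
  s_th <- make_theta_spectrum(6, 2, 1, TEST_DELTA, TEST_NGRID)
  acv_th <- spectrum_to_acv(s_th, 100)
  # sinusoidal: M_e = r_theta, mean 0
  env_s <- envelope_acv_theory(acv_th, coupling_spec("sinusoidal"))
  expect_equal(env_s$mean, 0)
  expect_equal(env_s$acv$values, acv_th$values)
  # constant gate weights (1, 0, ...): M_e == 1
  cst <- coupling_spec("pulsatile", weights = c(1, 0, 0))
  env_c <- envelope_acv_theory(acv_th, cst)
  expect_equal(env_c$mean, 1)
  expect_equal(env_c$acv$values, rep(1, 101))
  # K = 4 gate: Monte-Carlo check on a long theta path
  cp <- coupling_spec("pulsatile")
  env_t <- envelope_acv_theory(acv_th, cp)
  n <- 100000
  th <- circulant_draw(spectrum_to_acv(make_theta_spectrum(6, 2, 1, TEST_DELTA, 8192L),
                                       2000), n, 13)
  ev <- envelope(th, cp, theta_var = 1)$values
  for (l in c(0, 10, 40)) {
    prods <- ev[1:(n - l)] * ev[(1 + l):n]
    # serial correlation inflates the naive SE; use a generous block-based SE
    blocks <- tapply(prods, (seq_along(prods) - 1) %/% 2000, mean)
    se <- stats::sd(blocks) / sqrt(length(blocks))
    expect_lt(abs(mean(prods) - env_t$acv$values[l + 1]), 4 * se)
  }
  expect_gt(env_t$mean, 0)
})

test_that("gamma_acv_theory factorizes gate moments against x", {
  s_th <- make_theta_spectrum(6, 2, 1, TEST_DELTA, TEST_NGRID)
  s_x <- make_band_spectrum(100, 140, 1, 4, TEST_DELTA, TEST_NGRID)
  acv_th <- spectrum_to_acv(s_th, 100)
  acv_x <- spectrum_to_acv(s_x, 100)
  # sinusoidal: elementwise product of the two acvs
  g_s <- gamma_acv_theory(acv_th, acv_x, coupling_spec("sinusoidal"))
  expect_equal(g_s$values, acv_th$values * acv_x$values)
  # white x: gamma white with variance M_e(0) * r_x(0)
  white_x <- acv_seq(c(2, rep(0, 100)), TEST_DELTA)
  cp <- coupling_spec("pulsatile")
  g_w <- gamma_acv_theory(acv_th, white_x, cp)
  me0 <- envelope_acv_theory(acv_th, cp)$acv$values[1]
  expect_equal(g_w$values[1], 2 * me0)
  expect_true(all(g_w$values[-1] == 0))
})

test_that("preferred phase reports both printed and conventional forms", {
  expect_equal(unlist(preferred_phase(coupling_spec("pulsatile", tau = 0L), 0.001)),
               c(printed = 0, conventional_rad = 0))
  p <- preferred_phase(coupling_spec("pulsatile", tau = 1L, f_theta = 6), 0.001)
  expect_equal(p$printed, 1 / (12 * pi))
  p42 <- preferred_phase(coupling_spec("pulsatile", tau = 42L, f_theta = 6), 0.001)
  expect_equal(p42$conventional_rad, 2 * pi * 6 * 42 * 0.001)
  expect_equal(p42$conventional_rad / pi, 0.504)
})

test_that("harmonic spacing doubles from pulsatile to biphasic and flags degenerate input", {
  n <- 20000
  tt <- (0:(n - 1)) * TEST_DELTA
  th_det <- sample_path(sqrt(2) * cos(2 * pi * 6 * tt), TEST_DELTA, variance = 1)
  hp <- harmonic_spacing(periodogram(envelope(th_det, coupling_spec("pulsatile"),
                                              theta_var = 1)))
  hb <- harmonic_spacing(periodogram(envelope(th_det, coupling_spec("biphasic"),
                                              theta_var = 1)))
  df <- 1 / (n * TEST_DELTA)
  expect_equal(hp, 6, tolerance = 2 * df / 6)
  expect_equal(hb / hp, 2, tolerance = 2 * df / 12)
  # pure tone: single peak, so no spacing
  tone <- periodogram(sample_path(sin(2 * pi * 6 * tt), TEST_DELTA))
  expect_error(harmonic_spacing(tone), "fewer than 2")
})

test_that("deterministic pulsatile gate is periodic with the inverse harmonic spacing", {
  n <- 20000
  tt <- (0:(n - 1)) * TEST_DELTA
  th_det <- sample_path(sqrt(2) * cos(2 * pi * 6 * tt), TEST_DELTA, variance = 1)
  e <- envelope(th_det, coupling_spec("pulsatile"), theta_var = 1)
  spacing <- harmonic_spacing(periodogram(e))
  period <- round(1 / spacing / TEST_DELTA)
  shifted_dev <- max(abs(e$values[1:(n - period)] - e$values[(period + 1):n]))
  expect_lt(shifted_dev, 0.02 * diff(range(e$values)))
})
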