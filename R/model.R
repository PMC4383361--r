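# The composite observation process y = theta + gamma + eta.
#
# theta, x, eta are independent WSS Gaussian components drawn from separate
# seeded substreams; gamma = gate(theta) * x; y sums theta, gamma, eta.
# Additivity of independent zero-mean components gives
#   r_y = r_theta + r_gamma + r_eta,   S_y = S_theta + S_gamma + S_eta.

#' Construct a full model configuration
#'
#' Bundles the component spectra parameters, the coupling specification and
#' the simulation controls. Component amplitudes are free parameters of the
#' model; the defaults place the background an order of magnitude below the
#' theta peak at the theta frequency (`eta_rel = 0.1` in density) and give
#' gamma a tenth of theta's variance (`gamma_rel = 0.1`), which makes the
#' standard spectral structure (theta peak, 1/f background, gamma bump)
#' visible. Set `x_variance` / `eta_variance` directly to override.
#'
#' @param delta Sample period in s (default 0.001).
#' @param n Path length in samples (default 1000).
#' @param theta_center_f,theta_peak_width,theta_variance Theta spectrum
#'   parameters (Hz, Hz, variance).
#' @param x_f_lo,x_f_hi,x_edge_width Latent-process band edges and rolloff, Hz.
#' @param x_variance Latent-process variance, or `NA` to derive from
#'   `gamma_rel`.
#' @param eta_alpha,eta_floor_f Background exponent and low-frequency floor.
#' @param eta_variance Background variance, or `NA` to derive from `eta_rel`.
#' @param gamma_rel Target ratio `r_gamma(0) / r_theta(0)` used when
#'   `x_variance` is `NA` (default 0.1).
#' @param eta_rel Target ratio `S_eta(f_theta) / S_theta(f_theta)` used when
#'   `eta_variance` is `NA` (default 0.1).
#' @param coupling A `coupling_spec`; default pulsatile at `theta_center_f`.
#' @param ensemble_size Number of realizations (default 500).
#' @param base_seed Integer master seed (default 1).
#' @param n_grid Frequency-grid size for all spectra (default 8192).
#' @return An object of class `model_config`.
#' @export
model_config <- function(delta = 0.001, n = 1000L,
                         theta_center_f = 6, theta_peak_width = 2,
                         theta_variance = 1,
                         x_f_lo = 100, x_f_hi = 140, x_edge_width = 4,
                         x_variance = NA_real_,
                         eta_alpha = 2, eta_floor_f = 0.5,
                         eta_variance = NA_real_,
                         gamma_rel = 0.1, eta_rel = 0.1,
                         coupling = NULL,
                         ensemble_size = 500L, base_seed = 1L,
                         n_grid = 8192L) {
  if (is.null(coupling)) {
    coupling <- coupling_spec("pulsatile", f_theta = theta_center_f)
  }
  stopifnot(inherits(coupling, "coupling_spec"))
  if (ensemble_size < 1L) stop("ensemble_size must be at least 1")
  s_theta <- make_theta_spectrum(theta_center_f, theta_peak_width,
                                 theta_variance, delta, n_grid)
  if (is.na(eta_variance)) {
    s_eta_unit <- make_noise_spectrum(eta_alpha, 1, eta_floor_f, delta, n_grid)
    at_f <- function(s, f) s$power[which.min(abs(s$freqs - f))]
    eta_variance <- eta_rel * at_f(s_theta, theta_center_f) /
      at_f(s_eta_unit, theta_center_f)
  }
  if (is.na(x_variance)) {
    if (coupling$kind == "sinusoidal") {
      # r_gamma(0) = r_theta(0) * r_x(0), so r_x(0) = gamma_rel
      x_variance <- gamma_rel
    } else {
      # r_gamma(0) = M_e(0) * r_x(0) with M_e from the unit-variance gate
      acv_th <- spectrum_to_acv(s_theta, 0L)
      me0 <- envelope_acv_theory(acv_th, coupling)$acv$values[1]
      x_variance <- gamma_rel * theta_variance / me0
    }
  }
  # validate the remaining component specs now, so that e.g. Nyquist
  # violations surface at configuration time rather than at first use
  make_band_spectrum(x_f_lo, x_f_hi, x_variance, x_edge_width, delta, 65L)
  make_noise_spectrum(eta_alpha, eta_variance, eta_floor_f, delta, 65L)
  structure(list(
    delta = delta, n = as.integer(n), n_grid = as.integer(n_grid),
    theta = list(center_f = theta_center_f, peak_width = theta_peak_width,
                 variance = theta_variance),
    x = list(f_lo = x_f_lo, f_hi = x_f_hi, edge_width = x_edge_width,
             variance = x_variance),
    eta = list(alpha = eta_alpha, floor_f = eta_floor_f,
               variance = eta_variance),
    coupling = coupling,
    ensemble_size = as.integer(ensemble_size),
    base_seed = as.integer(base_seed)
  ), class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<model_config>  n = %d @ %g s, ensemble %d, seed %d\n",
    "  theta: %g Hz (fwhm %g), var %.4g | x: %g-%g Hz, var %.4g | ",
    "eta: 1/f^%g, var %.4g\n  coupling: %s (tau = %d)\n"),
    x$n, x$delta, x$ensemble_size, x$base_seed,
    x$theta$center_f, x$theta$peak_width, x$theta$variance,
    x$x$f_lo, x$x$f_hi, x$x$variance, x$eta$alpha, x$eta$variance,
    x$coupling$kind, x$coupling$tau))
  invisible(x)
}

#' Component spectra of a configuration
#'
#' @param config A `model_config`.
#' @return Named list of `spectrum_spec`: `theta`, `x`, `eta`.
#' @export
component_spectra <- function(config) {
  stopifnot(inherits(config, "model_config"))
  list(
    theta = make_theta_spectrum(config$theta$center_f, config$theta$peak_width,
                                config$theta$variance, config$delta, config$n_grid),
    x = make_band_spectrum(config$x$f_lo, config$x$f_hi, config$x$variance,
                           config$x$edge_width, config$delta, config$n_grid),
    eta = make_noise_spectrum(config$eta$alpha, config$eta$variance,
                              config$eta$floor_f, config$delta, config$n_grid)
  )
}

#' Simulate the full model: per-component ensembles of theta, x, eta, gamma, y
#'
#' theta, x and eta ensembles are drawn independently (substreams derived
#' from `base_seed`); each gamma realization is the gated product of the
#' matching theta and x realizations, and y sums theta, gamma and eta. When
#' the coupling lag `tau` is nonzero, all five ensembles are trimmed to the
#' common window on which the lagged gate is defined, so members stay equal
#' length.
#'
#' @param config A `model_config`.
#' @return Named list of `ensemble`: `theta`, `x`, `eta`, `gamma`, `y`.
#' @export
simulate_y <- function(config) {
  stopifnot(inherits(config, "model_config"))
  specs <- component_spectra(config)
  seeds <- derive_seeds(config$base_seed, 3L)
  m <- config$ensemble_size
  ens_th <- simulate_ensemble(specs$theta, config$n, m, seeds[1])
  ens_x <- simulate_ensemble(specs$x, config$n, m, seeds[2])
  ens_eta <- simulate_ensemble(specs$eta, config$n, m, seeds[3])

  tau <- config$coupling$tau
  valid <- seq.int(max(1L, 1L - tau), min(config$n, config$n - tau))
  trim <- function(p, keep) sample_path(p$values[keep], p$delta, p$label,
                                        p$seed, p$variance)
  g_paths <- vector("list", m)
  y_paths <- vector("list", m)
  for (j in seq_len(m)) {
    g <- make_gamma(ens_th$paths[[j]], ens_x$paths[[j]], config$coupling,
                    theta_var = config$theta$variance)
    g <- trim(g, valid)
    th <- trim(ens_th$paths[[j]], valid)
    et <- trim(ens_eta$paths[[j]], valid)
    g_paths[[j]] <- g
    y_paths[[j]] <- sample_path(th$values + g$values + et$values, config$delta,
                                label = "y", seed = ens_th$paths[[j]]$seed)
  }
  if (tau != 0L) {
    ens_th <- ensemble(lapply(ens_th$paths, trim, keep = valid), ens_th$base_seed)
    ens_x <- ensemble(lapply(ens_x$paths, trim, keep = valid), ens_x$base_seed)
    ens_eta <- ensemble(lapply(ens_eta$paths, trim, keep = valid), ens_eta$base_seed)
  }
  list(theta = ens_th, x = ens_x, eta = ens_eta,
       gamma = ensemble(g_paths, base_seed = config$base_seed),
       y = ensemble(y_paths, base_seed = config$base_seed))
}

#' Theoretical autocovariance of y
#'
#' Additivity over independent zero-mean components:
#' `r_y = r_theta + r_gamma + r_eta`, with `r_gamma` from
#' [gamma_acv_theory()].
#'
#' @param config A `model_config`.
#' @param max_lag Largest lag (default `n - 1`, capped by the grid limit).
#' @return An `acv_seq` labelled `"y"`.
#' @export
acv_y_theory <- function(config, max_lag = NULL) {
  stopifnot(inherits(config, "model_config"))
  specs <- component_spectra(config)
  cap <- (config$n_grid - 1L) %/% 2L
  if (is.null(max_lag)) max_lag <- min(config$n - 1L, cap)
  acv_th <- spectrum_to_acv(specs$theta, max_lag)
  acv_x <- spectrum_to_acv(specs$x, max_lag)
  acv_eta <- spectrum_to_acv(specs$eta, max_lag)
  acv_g <- gamma_acv_theory(acv_th, acv_x, config$coupling)
  acv_seq(acv_th$values + acv_g$values + acv_eta$values, config$delta,
          label = "y")
}

#' Theoretical spectrum of y
#'
#' `S_y = S_theta + S_gamma + S_eta`. For the sinusoidal kind `S_gamma` is
#' the frequency-domain convolution of `S_theta` and `S_x` (convolution
#' theorem for a plain product of independent processes); for the polynomial
#' kinds it is computed lag-domain-first (exact Wick autocovariance, then
#' transformed), since the single convolution only covers the linear gate.
#'
#' @param config A `model_config`.
#' @param acv_lags Lag-domain truncation used for the polynomial route
#'   (default 2000; the gamma autocovariance decays on the scale of
#'   `1/bandwidth`, a few tens of ms).
#' @return A `spectrum_spec` labelled `"y"`.
#' @export
spectrum_y_theory <- function(config, acv_lags = 2000L) {
  stopifnot(inherits(config, "model_config"))
  specs <- component_spectra(config)
  if (config$coupling$kind == "sinusoidal") {
    s_gamma <- convolve_spectra(specs$theta, specs$x, label = "gamma")
  } else {
    cap <- (config$n_grid - 1L) %/% 2L
    max_lag <- min(acv_lags, cap)
    acv_th <- spectrum_to_acv(specs$theta, max_lag)
    acv_x <- spectrum_to_acv(specs$x, max_lag)
    acv_g <- gamma_acv_theory(acv_th, acv_x, config$coupling)
    s_gamma <- acv_to_spectrum(acv_g, config$n_grid)
  }
  spectrum_spec(specs$theta$freqs,
                specs$theta$power + s_gamma$power + specs$eta$power,
                config$delta, label = "y")
}

#' Run the ensemble spectral experiment
#'
#' Simulates the configured ensemble of y, averages Hann-tapered
#' periodograms, and reports the quantities used to characterize the model:
#' the low-band spectral peak (theta), the high-band peak (gamma center
#' frequency), the background log-log slope, and the median gamma pulse
#' duration, alongside the theoretical spectrum.
#'
#' @param config A `model_config` with `ensemble_size >= 2`.
#' @param low_band,high_band,slope_band Measurement bands in Hz.
#' @return List with `estimate` (`spectrum_estimate`), `theory`
#'   (`spectrum_spec`), and `report` (named list of scalar measurements).
#' @export
run_experiment <- function(config, low_band = c(1, 30),
                           high_band = c(80, 160),
                           slope_band = c(150, 450)) {
  stopifnot(inherits(config, "model_config"))
  if (config$ensemble_size < 2L) stop("ensemble_size must be at least 2")
  sims <- simulate_y(config)
  est <- average_spectra(sims$y, taper = "hann")
  theory <- spectrum_y_theory(config)
  gamma_long <- sims$gamma$paths[[1]]
  durations <- tryCatch(
    measure_pulse_durations(gamma_long, c(config$x$f_lo, config$x$f_hi),
                            cycle_s = 1 / config$coupling$f_theta),
    error = function(e) numeric(0))
  report <- list(
    coupling = config$coupling$kind,
    # peak of the theta component's own averaged spectrum: tracks the
    # configured rhythm frequency regardless of how strong the 1/f
    # background is at the low edge of the band
    theta_peak_hz = find_peak(average_spectra(sims$theta, taper = "hann"),
                              low_band),
    # global argmax of S_y over low_band: can sit at the band edge when the
    # 1/f background dominates there (amplitude-dependent; documented)
    low_peak_hz = find_peak(est, low_band),
    high_peak_hz = find_peak(est, high_band),
    background_slope = fit_loglog_slope(est, slope_band),
    median_pulse_duration_s = if (length(durations)) stats::median(durations)
                              else NA_real_,
    n_avg = est$n_avg
  )
  list(estimate = est, theory = theory, report = report)
}
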