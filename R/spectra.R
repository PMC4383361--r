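# Component spectra and the discrete-time Wiener-Khintchine transform.
#
# All spectra are two-sided power spectral densities (units: variance * s)
# sampled on a uniform symmetric frequency grid over [-f_N, +f_N], where
# f_N = 1/(2*delta) is the Nyquist frequency for sample period delta (s).
# The process variance is r_0 = delta * integral(S df), evaluated by the
# trapezoid rule on the grid.

#' Uniform symmetric frequency grid
#'
#' Builds the frequency grid on which all spectra in this package live:
#' uniform over \eqn{[-f_N, +f_N]} with both endpoints and 0 included. The
#' number of points is forced odd so that the grid is exactly symmetric;
#' `n_grid` is rounded up by one when even.
#'
#' @param delta Sample period in seconds.
#' @param n_grid Requested number of grid points (default 8192).
#' @return Numeric vector of frequencies in Hz.
#' @keywords internal
spectrum_grid <- function(delta, n_grid = 8192L) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0)
  n_grid <- as.integer(n_grid)
  if (n_grid < 9L) stop("n_grid too small (need >= 9)")
  if (n_grid %% 2L == 0L) n_grid <- n_grid + 1L
  f_nyq <- 1 / (2 * delta)
  seq(-f_nyq, f_nyq, length.out = n_grid)
}

#' Construct a spectrum_spec
#'
#' Low-level constructor for the two-sided spectral density container.
#' Checks evenness, nonnegativity and grid uniformity.
#'
#' @param freqs Frequency grid from [spectrum_grid()].
#' @param power Nonnegative density values at `freqs` (variance * s).
#' @param delta Sample period in seconds.
#' @param label Component name (e.g. `"theta"`).
#' @param params Optional named list of builder parameters (kept as metadata).
#' @return An object of class `spectrum_spec`.
#' @export
spectrum_spec <- function(freqs, power, delta, label = "unnamed", params = list()) {
  stopifnot(length(freqs) == length(power), delta > 0)
  if (any(!is.finite(power))) stop("spectrum power must be finite")
  tol <- 1e-8 * max(abs(power), 1e-300)
  if (any(power < -tol)) stop("spectrum power must be nonnegative")
  power <- pmax(power, 0)
  df <- diff(freqs)
  if (max(abs(df - df[1])) > 1e-9 * abs(df[1])) stop("frequency grid must be uniform")
  if (min(abs(freqs)) > 1e-9) stop("frequency grid must contain f = 0")
  # even symmetry: grid is symmetric, so reversal maps f -> -f
  if (max(abs(power - rev(power))) > 1e-6 * max(power, 1e-300)) {
    stop("spectrum must be even: power(-f) == power(f)")
  }
  structure(
    list(freqs = as.numeric(freqs), power = as.numeric(power),
         delta = as.numeric(delta), label = as.character(label),
         params = params),
    class = "spectrum_spec"
  )
}

#' @export
print.spectrum_spec <- function(x, ...) {
  cat(sprintf("<spectrum_spec '%s'>  %d grid points, f_N = %g Hz, delta = %g s\n",
              x$label, length(x$freqs), max(x$freqs), x$delta))
  cat(sprintf("  variance r_0 = %.6g\n", spectrum_variance(x)))
  invisible(x)
}

# trapezoid quadrature weights for the spectrum grid (endpoints half-weight)
trapz_weights <- function(freqs) {
  df <- freqs[2] - freqs[1]
  w <- rep(df, length(freqs))
  w[c(1L, length(freqs))] <- df / 2
  w
}

#' Process variance implied by a spectrum
#'
#' Evaluates \eqn{r_0 = \Delta \int S(f)\,df} by trapezoid quadrature.
#'
#' @param spec A `spectrum_spec`.
#' @return Scalar variance.
#' @export
spectrum_variance <- function(spec) {
  stopifnot(inherits(spec, "spectrum_spec"))
  spec$delta * sum(trapz_weights(spec$freqs) * spec$power)
}

# scale power so that delta * trapz(power) == variance exactly
normalize_spectrum_power <- function(freqs, power, delta, variance) {
  mass <- delta * sum(trapz_weights(freqs) * power)
  if (mass <= 0) stop("spectrum has zero total power; cannot normalize")
  power * (variance / mass)
}

#' Construct an autocovariance sequence
#'
#' One-sided storage of an even autocovariance sequence \eqn{r_\tau}
#' (lags 0..L); two-sided values follow by symmetry \eqn{r_{-\tau}=r_\tau}.
#'
#' @param values Covariance at lags `0:(length(values)-1)`.
#' @param delta Sample period in seconds.
#' @param label Component name.
#' @return An object of class `acv_seq`.
#' @export
acv_seq <- function(values, delta, label = "unnamed") {
  stopifnot(delta > 0, length(values) >= 1L)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("autocovariance values must be finite")
  if (values[1] < 0) stop("r_0 must be nonnegative")
  if (any(abs(values) > values[1] * (1 + 1e-8) + 1e-12)) {
    stop("Cauchy-Schwarz violated: |r_tau| exceeds r_0")
  }
  structure(list(lags = seq_along(values) - 1L, values = values,
                 delta = as.numeric(delta), label = as.character(label)),
            class = "acv_seq")
}

#' @export
print.acv_seq <- function(x, ...) {
  cat(sprintf("<acv_seq '%s'>  lags 0..%d, delta = %g s, r_0 = %.6g\n",
              x$label, max(x$lags), x$delta, x$values[1]))
  invisible(x)
}

#' Theta-rhythm spectrum: a symmetric pair of Gaussian-profile peaks
#'
#' The slow-rhythm component is specified in the frequency domain as a pair of
#' Gaussian bumps at \eqn{\pm}`center_f` with full width at half maximum
#' `peak_width`, normalized so that the total integrated power (the process
#' variance \eqn{r_0}) equals `variance`. A 2 Hz-wide peak centered at 6 Hz is
#' the default configuration used throughout.
#'
#' @param center_f Peak center frequency in Hz (0 < center_f < f_N).
#' @param peak_width Full width at half maximum of each peak, Hz.
#' @param variance Total process variance (r_0).
#' @param delta Sample period in seconds (default 0.001, i.e. f_N = 500 Hz).
#' @param n_grid Number of frequency-grid points.
#' @return A `spectrum_spec` labelled `"theta"`.
#' @export
make_theta_spectrum <- function(center_f = 6, peak_width = 2, variance = 1,
                                delta = 0.001, n_grid = 8192L) {
  f_nyq <- 1 / (2 * delta)
  if (!(center_f > 0 && center_f < f_nyq)) stop("center_f must lie in (0, f_N)")
  if (peak_width <= 0) stop("peak_width must be positive")
  if (variance <= 0) stop("variance must be positive")
  if (center_f + peak_width / 2 >= f_nyq) {
    stop(sprintf("Nyquist violation: center_f + peak_width/2 = %g >= f_N = %g Hz",
                 center_f + peak_width / 2, f_nyq))
  }
  freqs <- spectrum_grid(delta, n_grid)
  sigma <- peak_width / (2 * sqrt(2 * log(2)))
  power <- exp(-(freqs - center_f)^2 / (2 * sigma^2)) +
    exp(-(freqs + center_f)^2 / (2 * sigma^2))
  power <- normalize_spectrum_power(freqs, power, delta, variance)
  spectrum_spec(freqs, power, delta, label = "theta",
                params = list(center_f_hz = center_f, peak_width_hz = peak_width,
                              variance = variance))
}

#' Background-noise spectrum with 1/f^alpha decay
#'
#' Pink/brown background activity: \eqn{S(f) \propto 1/|f|^\alpha} for
#' \eqn{|f| \ge} `floor_f`, held constant at the power-law value below
#' `floor_f` so that the spectrum is integrable, then normalized to the
#' requested total variance.
#'
#' @param alpha Power-law exponent (> 0); `alpha = 2` is the default used in
#'   the full model.
#' @param variance Total process variance.
#' @param floor_f Low-frequency flattening point in Hz (default 0.5).
#' @param delta Sample period in seconds.
#' @param n_grid Number of frequency-grid points.
#' @return A `spectrum_spec` labelled `"eta"`.
#' @export
make_noise_spectrum <- function(alpha = 2, variance = 1, floor_f = 0.5,
                                delta = 0.001, n_grid = 8192L) {
  if (alpha <= 0) stop("alpha must be positive (alpha = 0 would be white, not 1/f)")
  if (variance <= 0) stop("variance must be positive")
  f_nyq <- 1 / (2 * delta)
  if (!(floor_f > 0 && floor_f < f_nyq)) stop("floor_f must lie in (0, f_N)")
  freqs <- spectrum_grid(delta, n_grid)
  power <- ifelse(abs(freqs) >= floor_f, pmax(abs(freqs), 1e-12)^(-alpha),
                  floor_f^(-alpha))
  power <- normalize_spectrum_power(freqs, power, delta, variance)
  spectrum_spec(freqs, power, delta, label = "eta",
                params = list(alpha = alpha, floor_f_hz = floor_f,
                              variance = variance))
}

#' Band-limited latent-process spectrum
#'
#' The latent process x occupies a gamma-band frequency interval: the density
#' is constant on \eqn{\pm}[`f_lo`, `f_hi`] and rolls off to zero over
#' `edge_width` Hz with a raised-cosine taper outside the band (an exact
#' boxcar when `edge_width = 0`), then is normalized to `variance`. Defaults
#' give the high-gamma band 100-140 Hz.
#'
#' @param f_lo,f_hi Band edges in Hz, 0 < f_lo < f_hi < f_N.
#' @param variance Total process variance.
#' @param edge_width Raised-cosine rolloff width in Hz (default 4).
#' @param delta Sample period in seconds.
#' @param n_grid Number of frequency-grid points.
#' @return A `spectrum_spec` labelled `"x"`.
#' @export
make_band_spectrum <- function(f_lo = 100, f_hi = 140, variance = 1,
                               edge_width = 4, delta = 0.001, n_grid = 8192L) {
  f_nyq <- 1 / (2 * delta)
  if (!(f_lo > 0 && f_lo < f_hi)) stop("need 0 < f_lo < f_hi")
  if (f_hi >= f_nyq) {
    stop(sprintf("Nyquist violation: f_hi = %g >= f_N = %g Hz", f_hi, f_nyq))
  }
  if (edge_width < 0) stop("edge_width must be nonnegative")
  if (f_hi + edge_width >= f_nyq) {
    stop(sprintf("Nyquist violation: f_hi + edge_width = %g >= f_N = %g Hz",
                 f_hi + edge_width, f_nyq))
  }
  freqs <- spectrum_grid(delta, n_grid)
  af <- abs(freqs)
  power <- numeric(length(freqs))
  power[af >= f_lo & af <= f_hi] <- 1
  if (edge_width > 0) {
    lo_ramp <- af >= f_lo - edge_width & af < f_lo
    power[lo_ramp] <- 0.5 * (1 + cos(pi * (f_lo - af[lo_ramp]) / edge_width))
    hi_ramp <- af > f_hi & af <= f_hi + edge_width
    power[hi_ramp] <- 0.5 * (1 + cos(pi * (af[hi_ramp] - f_hi) / edge_width))
  }
  power <- normalize_spectrum_power(freqs, power, delta, variance)
  spectrum_spec(freqs, power, delta, label = "x",
                params = list(f_lo_hz = f_lo, f_hi_hz = f_hi,
                              edge_width_hz = edge_width, variance = variance))
}

#' Spectrum to autocovariance (discrete-time Wiener-Khintchine)
#'
#' Evaluates \eqn{r_\tau = \Delta \int_{-f_N}^{f_N} S(f) e^{i 2\pi f \tau
#' \Delta} df} by trapezoid quadrature on the periodic frequency grid. On the
#' uniform grid this quadrature is computed exactly with one FFT: with M
#' interior panels, \eqn{r_\tau = \Delta\,df\,(-1)^\tau \mathrm{IDFT}[S]_\tau}
#' for \eqn{0 \le \tau < M}. The imaginary residual is checked against
#' `1e-10 * r_0` (even spectra give a purely real result).
#'
#' @param spec A `spectrum_spec`.
#' @param max_lag Largest lag to return; must satisfy `max_lag <= n_grid/2`
#'   so that returned lags are unaffected by grid periodicity.
#' @return An `acv_seq` with lags `0:max_lag`.
#' @export
spectrum_to_acv <- function(spec, max_lag) {
  stopifnot(inherits(spec, "spectrum_spec"))
  max_lag <- as.integer(max_lag)
  if (max_lag < 0) stop("max_lag must be nonnegative")
  m_panels <- length(spec$freqs) - 1L   # periodic points; grid repeats at +f_N
  if (max_lag > m_panels %/% 2L) {
    stop(sprintf("max_lag = %d exceeds grid resolution limit n_grid/2 = %d",
                 max_lag, m_panels %/% 2L))
  }
  df <- spec$freqs[2] - spec$freqs[1]
  s_periodic <- spec$power[seq_len(m_panels)]  # drop +f_N duplicate of -f_N
  z <- stats::fft(s_periodic, inverse = TRUE)  # unscaled IDFT
  tau <- 0:max_lag
  r_complex <- spec$delta * df * (-1)^tau * z[tau + 1L]
  r0 <- Re(r_complex[1])
  if (max(abs(Im(r_complex))) > 1e-10 * max(r0, 1e-300)) {
    stop("imaginary residual in autocovariance exceeds tolerance; spectrum asymmetric?")
  }
  acv_seq(Re(r_complex), spec$delta, label = spec$label)
}

#' Autocovariance to spectrum (inverse Wiener-Khintchine direction)
#'
#' Discrete-time Fourier transform of the symmetrized sequence,
#' \eqn{S(f) = r_0 + 2\sum_{\tau \ge 1} r_\tau \cos(2\pi f \tau \Delta)},
#' evaluated on a fresh symmetric grid. Negative excursions are clipped to
#' zero: hard truncation of a sequence that has not decayed within its lag
#' range (e.g. a pure cosine) produces genuine negative Dirichlet sidelobes,
#' so ripple beyond `warn_tol` of the maximum triggers a warning rather
#' than an error.
#'
#' @param acv An `acv_seq`.
#' @param n_grid Number of frequency-grid points for the result.
#' @param warn_tol Relative negativity above which a clipping warning is
#'   issued (default `1e-3`).
#' @return A `spectrum_spec`.
#' @export
acv_to_spectrum <- function(acv, n_grid = 8192L, warn_tol = 1e-3) {
  stopifnot(inherits(acv, "acv_seq"))
  freqs <- spectrum_grid(acv$delta, n_grid)
  l <- length(acv$values)
  power <- rep(acv$values[1], length(freqs))
  if (l > 1L) {
    # chunk the lag sum to bound memory on long acvs
    chunk <- 512L
    for (start in seq(2L, l, by = chunk)) {
      idx <- start:min(start + chunk - 1L, l)
      tau <- idx - 1L
      power <- power + 2 * (cos(2 * pi * outer(freqs, tau) * acv$delta) %*%
                              acv$values[idx])[, 1]
    }
  }
  mx <- max(abs(power), 1e-300)
  if (any(power < -warn_tol * mx)) {
    warning(sprintf(
      "acv_to_spectrum: clipping negative spectral ripple (%.2g of max); %s",
      -min(power) / mx, "autocovariance truncated before decay?"))
  }
  spectrum_spec(freqs, pmax(power, 0), acv$delta, label = acv$label)
}

#' Convolution of two spectra on the periodic frequency domain
#'
#' Computes \eqn{S(f) = \Delta \int S_a(f') S_b(f - f')\,df'} as a circular
#' convolution over \eqn{[-f_N, f_N)}; by the discrete-time convolution
#' theorem this is the spectrum of a product of independent processes with
#' spectra `a` and `b`: its autocovariance is the lag-wise product of the
#' component autocovariances. The leading \eqn{\Delta} keeps the result on
#' the same density convention (\eqn{r_0 = \Delta \int S\,df}) as its
#' inputs, so that the output variance is the product of the input
#' variances. Implemented with FFTs on the periodic grid.
#'
#' @param a,b `spectrum_spec` objects sharing grid and delta.
#' @param label Label for the result.
#' @return A `spectrum_spec`.
#' @export
convolve_spectra <- function(a, b, label = "convolution") {
  stopifnot(inherits(a, "spectrum_spec"), inherits(b, "spectrum_spec"))
  if (abs(a$delta - b$delta) > 1e-12 || length(a$freqs) != length(b$freqs) ||
      max(abs(a$freqs - b$freqs)) > 1e-9) {
    stop("convolve_spectra: spectra must share the same grid and delta")
  }
  m <- length(a$freqs) - 1L   # periodic points
  df <- a$freqs[2] - a$freqs[1]
  ap <- a$power[seq_len(m)]
  bp <- b$power[seq_len(m)]
  # rotate b so index arithmetic lands on physical frequency (j-k)*df
  half <- m %/% 2L
  bp_rot <- c(bp[(half + 1L):m], bp[seq_len(half)])
  conv <- a$delta *
    Re(stats::fft(stats::fft(ap) * stats::fft(bp_rot), inverse = TRUE)) / m * df
  power <- c(conv, conv[1L])  # restore +f_N endpoint (periodic image of -f_N)
  mx <- max(abs(power), 1e-300)
  power <- pmax(power, 0)
  spectrum_spec(a$freqs, power, a$delta, label = label)
}

#' Write a spectrum or autocovariance as delimited text plus JSON metadata
#'
#' Spectra become two-column CSV (`frequency_hz,power`); autocovariances
#' become (`lag_s,covariance`). A `<stem>.json` sidecar records label, delta
#' and builder parameters.
#'
#' @param x A `spectrum_spec` or `acv_seq`.
#' @param stem Output path without extension; writes `<stem>.csv` and
#'   `<stem>.json`.
#' @return Invisibly, the paths written.
#' @export
write_spectrum_table <- function(x, stem) {
  csv <- paste0(stem, ".csv")
  meta <- paste0(stem, ".json")
  if (inherits(x, "spectrum_spec")) {
    utils::write.csv(data.frame(frequency_hz = x$freqs, power = x$power),
                     csv, row.names = FALSE)
    info <- list(kind = "spectrum", label = x$label, delta_s = x$delta,
                 variance = spectrum_variance(x), params = x$params)
  } else if (inherits(x, "acv_seq")) {
    utils::write.csv(data.frame(lag_s = x$lags * x$delta, covariance = x$values),
                     csv, row.names = FALSE)
    info <- list(kind = "acv", label = x$label, delta_s = x$delta,
                 variance = x$values[1])
  } else {
    stop("x must be a spectrum_spec or acv_seq")
  }
  jsonlite::write_json(info, meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, meta))
}
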