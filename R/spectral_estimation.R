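# Nonparametric spectrum estimation and the scalar band measurements
# (peak location, power-law slope, pulse durations, harmonic spacing).
#
# The estimator is a single Hann-tapered periodogram per realization,
# averaged across the ensemble. Power values estimate the TWO-SIDED density
# (same convention as spectrum_spec) reported on the one-sided grid [0, f_N],
# so averaged estimates are directly comparable with theoretical spectra.

#' Construct a spectrum_estimate
#'
#' @param freqs Frequency grid in Hz over `[0, f_N]`, monotone increasing.
#' @param power Estimated two-sided spectral density at `freqs`.
#' @param n_avg Number of realizations averaged.
#' @param taper Taper name.
#' @param delta Sample period in seconds.
#' @return An object of class `spectrum_estimate`.
#' @export
spectrum_estimate <- function(freqs, power, n_avg, taper, delta) {
  stopifnot(length(freqs) == length(power), n_avg >= 1, delta > 0)
  if (is.unsorted(freqs, strictly = TRUE)) stop("freqs must be strictly increasing")
  if (any(power < 0)) stop("power must be nonnegative")
  structure(list(freqs = freqs, power = power, n_avg = as.integer(n_avg),
                 taper = taper, delta = delta),
            class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate>  %d bins to %g Hz, %d realization(s), %s taper\n",
              length(x$freqs), max(x$freqs), x$n_avg, x$taper))
  invisible(x)
}

# taper window normalized to unit energy (sum of squares = 1)
taper_window <- function(n, taper = c("hann", "none")) {
  taper <- match.arg(taper)
  w <- switch(taper,
              hann = 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1))),
              none = rep(1, n))
  w / sqrt(sum(w^2))
}

# shared core: columns of `mat` are demeaned, tapered, transformed; returns
# the averaged two-sided density on the one-sided grid.
periodogram_matrix <- function(mat, delta, taper) {
  n <- nrow(mat)
  w <- taper_window(n, taper)
  u <- w * sweep(mat, 2, colMeans(mat))
  # |DFT|^2 of the unit-energy-tapered path estimates the two-sided density
  # on the package convention r_0 = delta * integral(S df):
  # delta * sum_k P_k df = sum_t u_t^2 (Parseval), df = 1/(n delta)
  spec_full <- Mod(stats::mvfft(u))^2
  n_keep <- n %/% 2L + 1L
  freqs <- (seq_len(n_keep) - 1L) / (n * delta)
  list(freqs = freqs, power = rowMeans(spec_full[seq_len(n_keep), , drop = FALSE]))
}

#' Hann-tapered periodogram of one sample path
#'
#' The path is demeaned, multiplied by a unit-energy taper, and transformed;
#' the returned values estimate the two-sided spectral density on `[0, f_N]`
#' in the package's density convention (`r_0 = delta * integral(S df)`).
#' Parseval holds exactly over the full two-sided transform: the
#' `delta * df`-weighted sum of two-sided power equals the energy of the
#' tapered path. A constant path yields an (allowed) all-zero estimate.
#'
#' @param path A `sample_path` with at least 64 samples and no `NA` values
#'   (trim the invalid gate edges first).
#' @param taper `"hann"` (default) or `"none"`.
#' @return A `spectrum_estimate` with `n_avg = 1`.
#' @export
periodogram <- function(path, taper = "hann") {
  stopifnot(inherits(path, "sample_path"))
  vals <- path$values
  if (anyNA(vals)) stop("path contains NA (invalid) samples; trim before estimating")
  n <- length(vals)
  if (n < 64L) stop("need at least 64 samples")
  pg <- periodogram_matrix(matrix(vals, ncol = 1L), path$delta, taper)
  spectrum_estimate(pg$freqs, pg$power, 1L, taper, path$delta)
}

#' Ensemble-averaged periodogram
#'
#' Arithmetic mean of per-realization tapered periodograms; the variance of
#' the averaged estimate shrinks like `1/n_avg`.
#'
#' @param ens An `ensemble` (size >= 2).
#' @param taper `"hann"` (default) or `"none"`.
#' @return A `spectrum_estimate`.
#' @export
average_spectra <- function(ens, taper = "hann") {
  stopifnot(inherits(ens, "ensemble"))
  m <- length(ens$paths)
  if (m < 2L) stop("ensemble_size must be at least 2")
  mat <- ensemble_matrix(ens)
  if (anyNA(mat)) stop("ensemble contains NA samples; trim before estimating")
  if (nrow(mat) < 64L) stop("need at least 64 samples")
  pg <- periodogram_matrix(mat, ens$delta, taper)
  spectrum_estimate(pg$freqs, pg$power, m, taper, ens$delta)
}

#' Peak frequency within a band
#'
#' Argmax of power within `band`, refined by three-point parabolic
#' interpolation so the answer is not quantized to the grid.
#'
#' @param est A `spectrum_estimate` or `spectrum_spec` (positive half used).
#' @param band Two-element numeric, Hz.
#' @return Peak frequency in Hz.
#' @export
find_peak <- function(est, band) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  freqs <- est$freqs
  power <- est$power
  if (inherits(est, "spectrum_spec")) {
    keep <- freqs >= 0
    freqs <- freqs[keep]; power <- power[keep]
  }
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (length(sel) == 0L) stop("band contains no frequency bins")
  i <- sel[which.max(power[sel])]
  if (i <= 1L || i >= length(freqs)) return(freqs[i])
  y1 <- power[i - 1L]; y2 <- power[i]; y3 <- power[i + 1L]
  denom <- y1 - 2 * y2 + y3
  offset <- if (abs(denom) < 1e-300) 0 else 0.5 * (y1 - y3) / denom
  offset <- max(min(offset, 0.5), -0.5)
  freqs[i] + offset * (freqs[2] - freqs[1])
}

#' Log-log power-law slope over a band
#'
#' Least-squares slope of `log10(power)` against `log10(f)` over `band`. An
#' exact power law `1/f^alpha` gives slope `-alpha`.
#'
#' @param est A `spectrum_estimate`.
#' @param band Two-element numeric, strictly positive Hz, covering at least
#'   10 bins.
#' @return Fitted slope (dimensionless).
#' @export
fit_loglog_slope <- function(est, band) {
  stopifnot(inherits(est, "spectrum_estimate"), length(band) == 2L)
  if (band[1] <= 0) stop("band must be strictly positive in frequency")
  sel <- which(est$freqs >= band[1] & est$freqs <= band[2])
  if (length(sel) < 10L) stop("need at least 10 bins in band")
  pos <- est$power[sel] > 0
  if (mean(!pos) > 0.2) stop("more than 20% of bins have nonpositive power")
  x <- log10(est$freqs[sel][pos])
  y <- log10(est$power[sel][pos])
  unname(stats::coef(stats::lm(y ~ x))[2])
}

# analytic band-pass: zero all DFT bins outside [f_lo, f_hi], double the
# retained positive-frequency bins; Mod() of the inverse transform is the
# band-limited amplitude envelope.
analytic_band_envelope <- function(values, delta, band) {
  n <- length(values)
  f <- (seq_len(n) - 1L) / (n * delta)
  f <- ifelse(f > 1 / (2 * delta), f - 1 / delta, f)  # signed bin frequencies
  keep <- f >= band[1] & f <= band[2]                  # positive side only
  spec <- stats::fft(values)
  spec[!keep] <- 0
  Mod(stats::fft(2 * spec, inverse = TRUE) / n)
}

#' Pulse durations of a gamma path
#'
#' Band-passes `gamma` to `band`, forms the analytic-signal amplitude
#' envelope, smooths it with a moving average of width `1/(2 * bandwidth)`
#' seconds, and segments pulses as maximal runs where the envelope exceeds
#' half the local (per-cycle) maximum. The slow-rhythm cycle length used for
#' the local maxima is `cycle_s`; if `NULL` it is estimated as the inverse of
#' the dominant sub-`band[1]/2` frequency of the envelope.
#'
#' @param gamma A `sample_path` (at least ~10 slow cycles long).
#' @param band Two-element numeric, Hz (e.g. `c(100, 140)`).
#' @param cycle_s Slow-rhythm period in seconds, or `NULL` to estimate.
#' @return Numeric vector of pulse durations in seconds.
#' @export
measure_pulse_durations <- function(gamma, band, cycle_s = NULL) {
  stopifnot(inherits(gamma, "sample_path"), length(band) == 2L, band[1] < band[2])
  vals <- gamma$values
  vals <- vals[!is.na(vals)]
  n <- length(vals)
  delta <- gamma$delta
  bandwidth <- band[2] - band[1]
  env <- analytic_band_envelope(vals, delta, band)
  k <- max(1L, round(1 / (2 * bandwidth) / delta))
  env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  if (is.null(cycle_s)) {
    est <- periodogram(sample_path(env, delta), taper = "hann")
    f_slow <- find_peak(est, c(0.5, band[1] / 2))
    cycle_s <- 1 / f_slow
  }
  cyc_len <- max(2L, round(cycle_s / delta))
  n_cyc <- ceiling(n / cyc_len)
  thresh <- numeric(n)
  for (c_i in seq_len(n_cyc)) {
    idx <- ((c_i - 1L) * cyc_len + 1L):min(c_i * cyc_len, n)
    thresh[idx] <- 0.5 * max(env[idx])
  }
  above <- env > thresh
  if (!any(above)) stop("no pulses detected; insufficient coupling depth")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  # drop runs touching the path boundary (truncated pulses)
  runs <- runs[starts[runs] > 1L & ends[runs] < n]
  if (length(runs) == 0L) stop("no complete pulses detected")
  r$lengths[runs] * delta
}
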