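# Phase-amplitude coupling: construction of gamma from theta and the latent
# band-limited process x, and its exact second-order theory.
#
# gamma_t = e_t * x_t with gate e_t a function of theta_{t+tau}:
#   sinusoidal: e_t = theta_{t+tau}
#   pulsatile:  e_t = sum_k w_k * z_{t+tau}^k        (one pulse per cycle)
#   biphasic:   e_t = sum_k w_k * (z_{t+tau}^2)^k    (two pulses per cycle)
# where z is theta normalized to unit variance (polynomial kinds only; the
# printed weights produce the intended pulse shape at that scale).
# Because x is independent of theta and zero-mean, gamma is zero-mean and
# r_gamma(tau') = E{e_t e_{t+tau'}} * r_x(tau'); the gate's raw cross-moment
# sequence follows in closed form from the Isserlis (Wick) theorem.

# Default polynomial gate weights for the K = 4 pulsatile/biphasic gates.
DEFAULT_COUPLING_WEIGHTS <- c(0.4783, 0.2625, 0.0933, 0.0292, 0.0058)

#' Construct a coupling specification
#'
#' @param kind One of `"sinusoidal"`, `"pulsatile"`, `"biphasic"`.
#' @param tau Integer coupling lag in samples (default 0: coupling at the
#'   theta peak). The gate at time t reads theta at t + tau.
#' @param weights Polynomial gate weights `w_0..w_K`; ignored by the
#'   sinusoidal kind. Default: the K = 4 weights
#'   (0.4783, 0.2625, 0.0933, 0.0292, 0.0058).
#' @param f_theta Theta center frequency in Hz, used for preferred-phase
#'   reporting and harmonic bookkeeping.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(kind = c("sinusoidal", "pulsatile", "biphasic"),
                          tau = 0L, weights = DEFAULT_COUPLING_WEIGHTS,
                          f_theta = 6) {
  kind <- match.arg(kind)
  weights <- as.numeric(weights)
  if (length(weights) < 1L || any(!is.finite(weights))) {
    stop("weights must be a nonempty finite numeric vector")
  }
  if (f_theta <= 0) stop("f_theta must be positive")
  structure(list(kind = kind, tau = as.integer(tau), weights = weights,
                 K = length(weights) - 1L, f_theta = as.numeric(f_theta),
                 harmonic_spacing = if (kind == "biphasic") 2 * f_theta else f_theta),
            class = "coupling_spec")
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf("<coupling_spec>  kind = %s, tau = %d, K = %d, f_theta = %g Hz\n",
              x$kind, x$tau, x$K, x$f_theta))
  if (x$kind != "sinusoidal") {
    cat("  weights:", paste(format(x$weights), collapse = ", "), "\n")
  }
  invisible(x)
}

# exponent of theta in term k of the gate polynomial
gate_power <- function(spec, k) {
  switch(spec$kind, pulsatile = k, biphasic = 2L * k,
         stop("gate_power undefined for sinusoidal kind"))
}

# resolve the theta variance used to normalize before polynomial gating
theta_norm_var <- function(theta, theta_var = NULL) {
  if (!is.null(theta_var)) return(theta_var)
  if (is.finite(theta$variance)) return(theta$variance)
  stats::var(theta$values[!is.na(theta$values)])
}

#' Coupling gate (variance envelope) from a theta path
#'
#' Evaluates the gate `e_t` on a theta sample path. Polynomial kinds
#' (pulsatile, biphasic) are applied to theta normalized to unit variance;
#' the sinusoidal kind uses theta as-is. Samples whose lagged index `t + tau`
#' falls outside the path are marked `NA` (invalid) rather than wrapped or
#' zero-padded, so downstream statistics can exclude them.
#'
#' @param theta A `sample_path` of the theta component.
#' @param spec A `coupling_spec`.
#' @param theta_var Variance used for normalization; defaults to the path's
#'   theoretical variance metadata, falling back to the sample variance.
#' @return A `sample_path` labelled `"envelope"`, same length as `theta`.
#' @export
envelope <- function(theta, spec, theta_var = NULL) {
  stopifnot(inherits(theta, "sample_path"), inherits(spec, "coupling_spec"))
  n <- length(theta$values)
  if (abs(spec$tau) >= n) stop("|tau| must be smaller than the path length")
  idx <- seq_len(n) + spec$tau
  shifted <- ifelse(idx >= 1L & idx <= n, theta$values[pmin(pmax(idx, 1L), n)], NA_real_)
  if (spec$kind == "sinusoidal") {
    e <- shifted
  } else {
    v <- theta_norm_var(theta, theta_var)
    if (!is.finite(v) || v <= 0) stop("theta variance for normalization must be positive")
    z <- shifted / sqrt(v)
    p <- gate_power(spec, 0:spec$K)
    e <- drop(outer(z, p, `^`) %*% spec$weights)
  }
  sample_path(e, theta$delta, label = "envelope", seed = theta$seed)
}

#' Construct gamma from theta and the latent process x
#'
#' `gamma_t = e_t * x_t` with the gate from [envelope()]. `x` must be
#' independent of `theta` (enforced by construction elsewhere: distinct RNG
#' substreams) and share its length and sample period.
#'
#' @param theta,x `sample_path` objects of equal length and delta.
#' @param spec A `coupling_spec`.
#' @param theta_var Optional normalization variance passed to [envelope()].
#' @return A `sample_path` labelled `"gamma"`; samples where the lagged gate
#'   is undefined are `NA`.
#' @export
make_gamma <- function(theta, x, spec, theta_var = NULL) {
  stopifnot(inherits(x, "sample_path"))
  if (length(theta$values) != length(x$values)) stop("theta and x lengths differ")
  if (abs(theta$delta - x$delta) > 1e-12) stop("theta and x sample periods differ")
  e <- envelope(theta, spec, theta_var = theta_var)
  sample_path(e$values * x$values, theta$delta, label = "gamma", seed = x$seed)
}

#' Gaussian cross moment E{a^j b^k} by the Isserlis (Wick) closed form
#'
#' For zero-mean jointly Gaussian `(a, b)` with common variance `r0` and
#' covariance `r_tau`, the moment expands over pair partitions: `m` cross
#' pairs contribute `r_tau^m` and the remaining within-variable pairs
#' contribute powers of `r0`, with the standard multiplicity
#' `j! k! / (m! 2^{(j-m)/2} ((j-m)/2)! 2^{(k-m)/2} ((k-m)/2)!)`.
#' Odd `j + k` gives 0.
#'
#' @param j,k Nonnegative integer exponents.
#' @param r0 Common variance.
#' @param r_tau Covariance between the two variables (`|r_tau| <= r0`).
#' @return The scalar moment.
#' @export
gaussian_cross_moment <- function(j, k, r0, r_tau) {
  j <- as.integer(j); k <- as.integer(k)
  if (j < 0 || k < 0) stop("exponents must be nonnegative")
  if (any(abs(r_tau) > r0 * (1 + 1e-8))) stop("|r_tau| must not exceed r0")
  if ((j + k) %% 2L == 1L) return(0 * r_tau)
  ms <- seq.int(j %% 2L, min(j, k), by = 2L)
  out <- 0 * r_tau
  for (m in ms) {
    mult <- factorial(j) * factorial(k) /
      (factorial(m) * 2^((j - m) / 2) * factorial((j - m) / 2) *
         2^((k - m) / 2) * factorial((k - m) / 2))
    out <- out + mult * r_tau^m * r0^((j + k - 2 * m) / 2)
  }
  out
}

# univariate Gaussian moment E{z^p}, z ~ N(0, r0): (p-1)!! r0^(p/2), 0 for odd p
gaussian_moment <- function(p, r0 = 1) {
  if (p %% 2L == 1L) return(0)
  if (p == 0L) return(1)
  prod(seq(1, p - 1, by = 2)) * r0^(p / 2)
}

#' Exact gate mean and raw cross-moment sequence
#'
#' For polynomial gates, computes the gate mean
#' \eqn{m_e = \sum_k w_k E\{z^{p(k)}\}} and the raw second-moment sequence
#' \eqn{M_e(\tau') = \sum_{k,l} w_k w_l E\{z_t^{p(k)} z_{t+\tau'}^{p(l)}\}}
#' by the Wick closed form, with `p(k) = k` (pulsatile) or `2k` (biphasic)
#' and z the unit-variance normalized theta. The raw (not mean-centered)
#' moment is returned because the gamma autocovariance factorizes through it.
#' The sinusoidal kind reduces to `M_e = r_theta`, `m_e = 0`.
#'
#' @param acv_theta An `acv_seq` for theta.
#' @param spec A `coupling_spec`.
#' @return List with `mean` (scalar) and `acv` (an `acv_seq` holding `M_e`).
#' @export
envelope_acv_theory <- function(acv_theta, spec) {
  stopifnot(inherits(acv_theta, "acv_seq"), inherits(spec, "coupling_spec"))
  if (spec$kind == "sinusoidal") {
    return(list(mean = 0,
                acv = acv_seq(acv_theta$values, acv_theta$delta, "envelope")))
  }
  r0 <- acv_theta$values[1]
  rhat <- acv_theta$values / r0   # normalized theta correlation sequence
  p <- gate_power(spec, 0:spec$K)
  m_e <- sum(spec$weights * vapply(p, gaussian_moment, 1))
  m_vals <- numeric(length(rhat))
  for (a in seq_along(p)) {
    for (b in seq_along(p)) {
      m_vals <- m_vals + spec$weights[a] * spec$weights[b] *
        gaussian_cross_moment(p[a], p[b], 1, rhat)
    }
  }
  env_acv <- structure(list(lags = acv_theta$lags, values = m_vals,
                            delta = acv_theta$delta, label = "envelope"),
                       class = "acv_seq")
  list(mean = m_e, acv = env_acv)
}

#' Theoretical autocovariance of gamma
#'
#' Independence of the gate (a function of theta) and the latent process x
#' factorizes the gamma autocovariance:
#' \eqn{r^{(\gamma)}_{\tau'} = M_e(\tau')\, r^{(x)}_{\tau'}}. Since
#' `E{x} = 0`, gamma is zero-mean and the raw moment is the covariance.
#'
#' @param acv_theta,acv_x `acv_seq` objects with matching delta.
#' @param spec A `coupling_spec`.
#' @return An `acv_seq` labelled `"gamma"`, truncated to the shorter lag range.
#' @export
gamma_acv_theory <- function(acv_theta, acv_x, spec) {
  stopifnot(inherits(acv_x, "acv_seq"))
  if (abs(acv_theta$delta - acv_x$delta) > 1e-12) stop("mismatched delta")
  env <- envelope_acv_theory(acv_theta, spec)
  l <- min(length(env$acv$values), length(acv_x$values))
  acv_seq(env$acv$values[seq_len(l)] * acv_x$values[seq_len(l)],
          acv_x$delta, label = "gamma")
}

#' Preferred coupling phase, in both printed and conventional forms
#'
#' The phase of theta at which the gate is maximal. Two values are reported:
#' `printed` uses the formula \eqn{\tau / (2 \pi f_\theta)} as it appears in
#' the source model description (dimensionally a time, not a radian phase),
#' and `conventional` is the standard radian phase \eqn{2 \pi f_\theta \tau
#' \Delta} accumulated by a `f_theta`-Hz oscillation over `tau` samples.
#' Both are returned; neither is silently preferred.
#'
#' @param spec A `coupling_spec`.
#' @param delta Sample period in seconds (used by the conventional form).
#' @return Named list `printed`, `conventional_rad`.
#' @export
preferred_phase <- function(spec, delta) {
  stopifnot(inherits(spec, "coupling_spec"), delta > 0)
  list(printed = spec$tau / (2 * pi * spec$f_theta),
       conventional_rad = 2 * pi * spec$f_theta * spec$tau * delta)
}

#' Median harmonic spacing of an envelope spectrum
#'
#' Detects harmonic peaks in a spectrum estimate and returns the median
#' spacing between successive detected peaks. Detection works on the
#' amplitude scale (square root of power, since the harmonic content of
#' smooth polynomial gates decays quickly with harmonic number) and keeps
#' local maxima whose topographic prominence — height above the higher of
#' the two valleys separating the peak from taller terrain — is at least
#' `prominence` of the tallest peak's amplitude, separated by at least
#' `min_sep_bins` bins. The f = 0 boundary bin may qualify. A pulsatile gate
#' of an `f_theta` rhythm shows peaks spaced by `f_theta`; the biphasic gate
#' doubles the spacing. Estimates from stochastic rhythms should be
#' ensemble-averaged first ([average_spectra()]): single periodograms are
#' too rough for peak detection.
#'
#' @param est A `spectrum_estimate` of a long envelope path.
#' @param prominence Relative prominence threshold (default 0.1).
#' @param min_sep_bins Minimum peak separation in bins (default 2).
#' @return Median spacing in Hz.
#' @export
harmonic_spacing <- function(est, prominence = 0.1, min_sep_bins = 2L) {
  stopifnot(inherits(est, "spectrum_estimate"))
  p <- sqrt(est$power)
  n <- length(p)
  is_max <- c(p[1] > p[2], p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n],
              p[n] > p[n - 1])
  cand <- which(is_max)
  prom <- vapply(cand, function(i) {
    left <- if (any(p[seq_len(i - 1)] > p[i])) {
      j <- max(which(p[seq_len(i - 1)] > p[i]))
      min(p[j:i])
    } else if (i > 1L) min(p[seq_len(i)]) else p[i]
    right <- if (any(p[seq.int(i, n)] > p[i])) {
      j <- i - 1L + min(which(p[seq.int(i, n)] > p[i]))
      min(p[i:j])
    } else if (i < n) min(p[seq.int(i, n)]) else p[i]
    base <- if (p[i] >= max(p)) min(left, right) else max(left, right)
    p[i] - base
  }, 1)
  keep <- cand[prom >= prominence * max(p)]
  # enforce separation, keeping taller peaks first
  keep <- keep[order(p[keep], decreasing = TRUE)]
  sep <- integer(0)
  for (i in keep) {
    if (all(abs(i - sep) >= min_sep_bins)) sep <- c(sep, i)
  }
  sep <- sort(sep)
  if (length(sep) < 2L) {
    stop("fewer than 2 harmonic peaks detected; insufficient data or no harmonics")
  }
  stats::median(diff(est$freqs[sep]))
}
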