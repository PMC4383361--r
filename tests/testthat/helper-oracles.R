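# Independent oracles used across tests. These deliberately avoid the code
# paths they check: brute-force enumeration, direct summation, plain
# quadrature.

# Gaussian moment by explicit enumeration of all pair partitions.
# cov_fn(a, b) returns the covariance of variables at positions a, b.
oracle_wick_enumeration <- function(n_vars, cov_fn) {
  recurse <- function(idx) {
    if (length(idx) == 0L) return(1)
    if (length(idx) %% 2L == 1L) return(0)
    tot <- 0
    a <- idx[1]
    for (j in 2:length(idx)) {
      tot <- tot + cov_fn(a, idx[j]) * recurse(idx[-c(1, j)])
    }
    tot
  }
  recurse(seq_len(n_vars))
}

# E{x^j y^k} for zero-mean Gaussians with var r0 and covariance r_tau.
oracle_cross_moment <- function(j, k, r0, r_tau) {
  cov_fn <- function(a, b) if ((a <= j) == (b <= j)) r0 else r_tau
  oracle_wick_enumeration(j + k, cov_fn)
}

# Wiener-Khintchine by plain trapezoid quadrature (no FFT).
oracle_quadrature_acv <- function(spec, lags) {
  df <- spec$freqs[2] - spec$freqs[1]
  w <- rep(df, length(spec$freqs))
  w[c(1, length(w))] <- df / 2
  vapply(lags, function(tau) {
    Re(spec$delta * sum(w * spec$power *
                          exp(1i * 2 * pi * spec$freqs * tau * spec$delta)))
  }, 1)
}

# Direct-summation DFT periodogram (no FFT), matching the package estimator
# convention: unit-energy taper, |DFT|^2 as two-sided density on [0, f_N].
oracle_direct_periodogram <- function(values, delta, taper_vals) {
  n <- length(values)
  u <- taper_vals * (values - mean(values))
  n_keep <- n %/% 2L + 1L
  freqs <- (seq_len(n_keep) - 1L) / (n * delta)
  power <- vapply(seq_len(n_keep) - 1L, function(k) {
    Mod(sum(u * exp(-1i * 2 * pi * k * (seq_len(n) - 1L) / n)))^2
  }, 1)
  list(freqs = freqs, power = power)
}

# sample autocovariance of an ensemble matrix (rows time, cols realizations)
# at the given lags; returns mean and standard error across realizations
sample_acv_se <- function(mat, lags) {
  n <- nrow(mat)
  m <- ncol(mat)
  t(vapply(lags, function(l) {
    prods <- colMeans(mat[1:(n - l), , drop = FALSE] *
                        mat[(1 + l):n, , drop = FALSE])
    c(mean = mean(prods), se = stats::sd(prods) / sqrt(m))
  }, c(mean = 1, se = 1)))
}

# small default grids keep unit tests fast
TEST_DELTA <- 0.001
TEST_NGRID <- 2048L
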