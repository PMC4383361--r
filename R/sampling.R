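# Exact simulation of WSS Gaussian sample paths.
#
# A length-n truncated realization of a zero-mean WSS Gaussian process with
# autocovariance r has covariance matrix R, Toeplitz with R[t, t+tau] = r_tau.
# Draw v ~ N(0, I_n) and form y = R^{1/2} v, where R^{1/2} is the symmetric
# (eigendecomposition) square root: cov(y) = R^{1/2} E{vv'} R^{1/2} = R.
# An independent circulant-embedding sampler serves as a cross-check.

#' Toeplitz covariance matrix of a WSS process
#'
#' @param acv An `acv_seq`. If it is defined out to fewer than `n - 1` lags it
#'   is zero-extended (with a message), which is exact whenever the
#'   autocovariance has effectively decayed.
#' @param n Path length (matrix dimension).
#' @return An `n x n` symmetric Toeplitz matrix.
#' @export
toeplitz_covariance <- function(acv, n) {
  stopifnot(inherits(acv, "acv_seq"))
  n <- as.integer(n)
  if (n <= 0) stop("n must be positive")
  r <- acv$values
  if (length(r) < n) {
    message(sprintf("zero-extending autocovariance '%s' from lag %d to lag %d",
                    acv$label, length(r) - 1L, n - 1L))
    r <- c(r, rep(0, n - length(r)))
  }
  stats::toeplitz(r[seq_len(n)])
}

#' Symmetric square root of a covariance matrix
#'
#' Eigendecomposition-based square root `V diag(sqrt(lambda)) V'`. Slightly
#' negative eigenvalues in `[-clip_tol * lambda_max, 0)` — routine for
#' truncated autocovariances of narrowband spectra — are clipped to zero;
#' anything more negative signals an invalid (non-positive-semidefinite)
#' autocovariance and raises an error.
#'
#' @param R Symmetric covariance matrix.
#' @param clip_tol Relative clipping tolerance (default `1e-10`).
#' @param delta Sample period carried as metadata.
#' @return An object of class `cov_factor` with fields `n`, `factor`,
#'   `clip_count`, `delta`.
#' @export
covariance_sqrt <- function(R, clip_tol = 1e-10, delta = NA_real_) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) stop("R must be a square matrix")
  if (max(abs(R - t(R))) > 1e-8 * max(abs(R), 1e-300)) stop("R must be symmetric")
  e <- eigen(R, symmetric = TRUE)
  lam <- e$values
  lam_max <- max(lam, 0)
  if (lam_max == 0 && all(lam == 0)) {
    fac <- matrix(0, nrow(R), ncol(R))
    return(structure(list(n = nrow(R), factor = fac, clip_count = 0L,
                          delta = delta), class = "cov_factor"))
  }
  bad <- lam < -clip_tol * lam_max
  if (any(bad)) {
    stop(sprintf(
      "covariance not PSD: eigenvalue %.3e below -clip_tol * lambda_max = %.3e",
      min(lam), -clip_tol * lam_max))
  }
  clip_count <- sum(lam < 0)
  lam <- pmax(lam, 0)
  fac <- e$vectors %*% (sqrt(lam) * t(e$vectors))
  fac <- (fac + t(fac)) / 2
  structure(list(n = nrow(R), factor = fac, clip_count = as.integer(clip_count),
                 delta = delta), class = "cov_factor")
}

#' @export
print.cov_factor <- function(x, ...) {
  cat(sprintf("<cov_factor>  n = %d, %d eigenvalue(s) clipped\n",
              x$n, x$clip_count))
  invisible(x)
}

#' Construct a sample_path
#'
#' @param values Real path values.
#' @param delta Sample period in seconds.
#' @param label Component name.
#' @param seed RNG provenance (integer or NA).
#' @param variance Theoretical process variance, when known; used e.g. to
#'   normalize theta before coupling polynomials are applied.
#' @return An object of class `sample_path`.
#' @export
sample_path <- function(values, delta, label = "unnamed", seed = NA_integer_,
                        variance = NA_real_) {
  values <- as.numeric(values)
  if (any(!is.finite(values) & !is.na(values))) stop("path values must be finite or NA")
  structure(list(values = values, delta = as.numeric(delta),
                 label = as.character(label), seed = seed, variance = variance),
            class = "sample_path")
}

#' @export
print.sample_path <- function(x, ...) {
  cat(sprintf("<sample_path '%s'>  n = %d, delta = %g s, seed = %s\n",
              x$label, length(x$values), x$delta, format(x$seed)))
  invisible(x)
}

#' Construct an ensemble of sample paths
#'
#' @param paths List of `sample_path` objects sharing length and delta.
#' @param base_seed Seed from which per-path substream seeds were derived.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(paths, base_seed = NA_integer_) {
  stopifnot(length(paths) >= 1L, all(vapply(paths, inherits, TRUE, "sample_path")))
  n <- length(paths[[1]]$values)
  d <- paths[[1]]$delta
  ok <- vapply(paths, function(p) length(p$values) == n && p$delta == d, TRUE)
  if (!all(ok)) stop("all ensemble members must share n and delta")
  structure(list(paths = paths, base_seed = base_seed,
                 label = paths[[1]]$label, n = n, delta = d),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble '%s'>  %d paths of length %d, delta = %g s\n",
              x$label, length(x$paths), x$n, x$delta))
  invisible(x)
}

#' Matrix view of an ensemble (rows = time, columns = realizations)
#' @param ens An `ensemble`.
#' @return Numeric matrix `n x m`.
#' @export
ensemble_matrix <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  vapply(ens$paths, function(p) p$values, numeric(ens$n))
}

# Derive m reproducible substream seeds from one base seed.
derive_seeds <- function(base_seed, m) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(base_seed))
  sample.int(2147483646L, m)
}

#' Draw one Gaussian sample path from a covariance factor
#'
#' `path = factor %*% v` with `v` i.i.d. standard normal from the seeded
#' generator; deterministic given the seed.
#'
#' @param factor A `cov_factor`.
#' @param rng_seed Integer seed.
#' @param label Component name for the path.
#' @param variance Theoretical variance metadata (optional).
#' @return A `sample_path`.
#' @export
draw_path <- function(factor, rng_seed, label = "unnamed", variance = NA_real_) {
  stopifnot(inherits(factor, "cov_factor"))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(rng_seed))
  v <- stats::rnorm(factor$n)
  sample_path(as.numeric(factor$factor %*% v), factor$delta, label = label,
              seed = as.integer(rng_seed), variance = variance)
}

#' Draw an ensemble from a covariance factor
#'
#' Per-path seeds are derived from `base_seed` so every member path is an
#' independent, individually reproducible substream.
#'
#' @param factor A `cov_factor`.
#' @param m Ensemble size.
#' @param base_seed Integer base seed.
#' @param label Component name.
#' @param variance Theoretical variance metadata.
#' @return An `ensemble`.
#' @export
draw_ensemble <- function(factor, m, base_seed, label = "unnamed",
                          variance = NA_real_) {
  stopifnot(inherits(factor, "cov_factor"), m >= 1L)
  seeds <- derive_seeds(base_seed, m)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  n <- factor$n
  v <- matrix(0, n, m)
  for (j in seq_len(m)) {
    set.seed(seeds[j])
    v[, j] <- stats::rnorm(n)
  }
  y <- factor$factor %*% v
  paths <- lapply(seq_len(m), function(j) {
    sample_path(y[, j], factor$delta, label = label, seed = seeds[j],
                variance = variance)
  })
  ensemble(paths, base_seed = as.integer(base_seed))
}

#' Simulate one component realization from its spectrum
#'
#' Composition `spectrum_to_acv` -> `toeplitz_covariance` -> `covariance_sqrt`
#' -> `draw_path`: the exact covariance-based sampler used for every
#' independently specified component (theta, x, eta). Gamma is never sampled
#' this way; it is constructed from theta and x realizations.
#'
#' @param spec A `spectrum_spec`.
#' @param n Path length.
#' @param rng_seed Integer seed.
#' @return A `sample_path`.
#' @export
simulate_component <- function(spec, n, rng_seed) {
  acv <- spectrum_to_acv(spec, max_lag = min(n - 1L, (length(spec$freqs) - 1L) %/% 2L))
  R <- toeplitz_covariance(acv, n)
  fac <- covariance_sqrt(R, delta = spec$delta)
  draw_path(fac, rng_seed, label = spec$label,
            variance = spectrum_variance(spec))
}

#' Simulate an ensemble of component realizations
#'
#' Same pipeline as [simulate_component()] with the covariance factor reused
#' across draws.
#'
#' @param spec A `spectrum_spec`.
#' @param n Path length.
#' @param m Ensemble size.
#' @param base_seed Integer base seed.
#' @return An `ensemble`.
#' @export
simulate_ensemble <- function(spec, n, m, base_seed) {
  acv <- spectrum_to_acv(spec, max_lag = min(n - 1L, (length(spec$freqs) - 1L) %/% 2L))
  R <- toeplitz_covariance(acv, n)
  fac <- covariance_sqrt(R, delta = spec$delta)
  draw_ensemble(fac, m, base_seed, label = spec$label,
                variance = spectrum_variance(spec))
}

#' Circulant-embedding draw of a WSS Gaussian path
#'
#' Independent exact sampler used to cross-validate the Toeplitz square-root
#' method and to generate long paths cheaply. The autocovariance (zero-
#' extended beyond its available lags) is embedded in a circulant of size
#' `M >= 2 (n - 1)`; the embedding eigenvalues are the real DFT of the
#' circulant's first row and must be nonnegative within tolerance. Supply
#' the autocovariance out to lags where it has effectively decayed:
#' truncating a still-correlated sequence makes the embedding indefinite and
#' raises an error, while the mild (~1e-5 relative) negative eigenvalues
#' produced by tail truncation of decayed sequences are clipped.
#'
#' @param acv An `acv_seq`.
#' @param n Path length.
#' @param rng_seed Integer seed.
#' @param tol Relative tolerance on negative embedding eigenvalues
#'   (default `1e-4`).
#' @return A `sample_path`.
#' @export
circulant_draw <- function(acv, n, rng_seed, tol = 1e-4) {
  stopifnot(inherits(acv, "acv_seq"))
  n <- as.integer(n)
  if (n <= 1L) stop("n must be at least 2")
  half <- max(n - 1L, length(acv$values) - 1L)
  m_embed <- 2L * half
  r <- c(acv$values, rep(0, half + 1L - length(acv$values)))[seq_len(half + 1L)]
  first_row <- c(r, rev(r[2:half]))
  lam <- Re(stats::fft(first_row))
  if (min(lam) < -tol * max(lam)) {
    stop(sprintf(
      "circulant embedding failed: eigenvalue %.3e below -tol * max = %.3e",
      min(lam), -tol * max(lam)))
  }
  lam <- pmax(lam, 0)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(rng_seed))
  xi <- stats::rnorm(m_embed)
  zeta <- stats::rnorm(m_embed)
  z <- sqrt(lam) * complex(real = xi, imaginary = zeta)
  path <- Re(stats::fft(z)) / sqrt(m_embed)
  sample_path(path[seq_len(n)], acv$delta, label = acv$label,
              seed = as.integer(rng_seed), variance = acv$values[1])
}

#' Write an ensemble as delimited text plus JSON metadata
#'
#' One CSV per ensemble (rows = time, columns = realizations) and a JSON
#' sidecar with label, n, delta, seeds.
#'
#' @param ens An `ensemble`.
#' @param stem Output path without extension.
#' @return Invisibly, the paths written.
#' @export
write_ensemble <- function(ens, stem) {
  stopifnot(inherits(ens, "ensemble"))
  csv <- paste0(stem, ".csv")
  meta <- paste0(stem, ".json")
  mat <- ensemble_matrix(ens)
  colnames(mat) <- sprintf("r%04d", seq_len(ncol(mat)))
  utils::write.csv(as.data.frame(mat), csv, row.names = FALSE)
  jsonlite::write_json(
    list(label = ens$label, n = ens$n, delta_s = ens$delta,
         ensemble_size = length(ens$paths), base_seed = ens$base_seed,
         path_seeds = vapply(ens$paths, function(p) as.integer(p$seed), 1L)),
    meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, meta))
}
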