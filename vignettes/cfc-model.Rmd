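---
title: "A stationary time-series model of phase-amplitude cross-frequency coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stationary time-series model of phase-amplitude cross-frequency coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfcsim)
```

## The model

Phase-amplitude cross-frequency coupling (CFC) is the tendency of the
amplitude envelope of a fast neural rhythm (gamma, here 100–140 Hz) to wax
and wane with the phase of a slow rhythm (theta, here 6 Hz). `cfcsim`
implements a family of weak-sense stationary (WSS) Gaussian-process models
in which this coupling is built in by construction, so that every
second-order property — autocovariance, spectrum, the effect of the coupling
nonlinearity — is available exactly, in closed form, alongside exact
simulation.

The observed process is a sum of three zero-mean WSS components,

$$y_t = \theta_t + \gamma_t + \eta_t,$$

* $\theta$: the slow rhythm, specified in the frequency domain as a pair of
  Gaussian-profile spectral peaks at $\pm f_\theta$ with a given full width
  at half maximum;
* $\eta$: $1/f^\alpha$ background activity ($\alpha = 2$ by default),
  flattened below a low-frequency floor so that its variance is finite;
* $\gamma$: the coupled fast rhythm, constructed as the product
  $\gamma_t = e_t \, x_t$ of a *gate* $e_t$ — a function of the (possibly
  lagged) slow rhythm — with a latent band-limited Gaussian process $x$
  independent of $\theta$.

Three gates are provided:

| kind        | gate $e_t$                               | effect on the gamma envelope            |
|-------------|------------------------------------------|-----------------------------------------|
| sinusoidal  | $\theta_{t+\tau}$                        | sinusoidally modulated variance          |
| pulsatile   | $\sum_{k=0}^{K} w_k z_{t+\tau}^{k}$      | one punctate burst per theta cycle       |
| biphasic    | $\sum_{k=0}^{K} w_k (z_{t+\tau}^{2})^{k}$ | two bursts per theta cycle               |

with $z$ the slow rhythm normalized to unit variance and, by default, the
$K = 4$ weights $w = (0.4783, 0.2625, 0.0933, 0.0292, 0.0058)$. Summing
powers of $z$ concentrates the gate into a pulse once (or, with even powers,
twice) per cycle; in the frequency domain the gate has harmonics spaced by
$f_\theta$ (pulsatile) or $2 f_\theta$ (biphasic), and a gate with harmonics
spaced by $f_0$ repeats with period $1/f_0$.

All spectra are two-sided densities $S(f)$ on a uniform symmetric grid over
$[-f_N, f_N]$, $f_N = 1/(2\Delta)$, tied to autocovariances by the
discrete-time Wiener–Khintchine relation

$$r_\tau = \Delta \int_{-f_N}^{f_N} S(f)\, e^{i 2 \pi f \tau \Delta}\, df ,$$

evaluated by trapezoid quadrature on the grid (computed exactly with one
FFT; a brute-force quadrature oracle checks this in the tests). Variances
are always quoted as $r_0$.

## Exact second-order theory of the coupled component

Because $x$ is independent of $\theta$ and zero-mean, $\gamma$ is zero-mean
regardless of the gate (even for the biphasic gate, whose own mean is
positive), and its autocovariance factorizes:

$$r^{(\gamma)}_{\tau'} \;=\; M_e(\tau')\, r^{(x)}_{\tau'}, \qquad
  M_e(\tau') = E\{e_t\, e_{t+\tau'}\}.$$

$M_e$ is a *raw* (uncentered) moment sequence: the factorization runs
through it, not through the centered gate covariance, which matters for the
biphasic gate. For polynomial gates each term
$E\{z_t^j z_{t+\tau'}^k\}$ is a Gaussian cross moment, computed in closed
form by the Isserlis (Wick) theorem as a sum over pair partitions;
`gaussian_cross_moment()` implements the closed form and the tests verify it
against brute-force enumeration of all pairings for $j + k \le 8$. For the
sinusoidal gate $M_e = r^{(\theta)}$ exactly.

Component independence then gives additivity,
$r^{(y)} = r^{(\theta)} + r^{(\gamma)} + r^{(\eta)}$ and
$S_y = S_\theta + S_\gamma + S_\eta$. For the sinusoidal gate $S_\gamma$ is
also available directly in the frequency domain as the circular convolution
$S_\gamma(f) = \Delta \int S_\theta(f') S_x(f - f')\, df'$; the leading
$\Delta$ is required for this route to agree with the lag-domain product —
the package computes both and the tests pin their equality. For polynomial
gates, $S_\gamma$ is computed lag-domain-first (Wick autocovariance, then
transformed), since a single convolution only covers the linear gate.

## Exact simulation

A length-$n$ realization of any independently specified component is drawn
as $\mathbf{y} = R^{1/2} \mathbf{v}$ with $\mathbf{v}$ i.i.d. standard
normal and $R$ the Toeplitz covariance matrix $R_{t,t+\tau} = r_\tau$. The
square root is the *symmetric* (eigendecomposition) root rather than a
Cholesky factor: it is what the identity
$R^{1/2} E\{\mathbf{v}\mathbf{v}^\top\} R^{1/2} = R$ presumes, and it
tolerates the numerically semidefinite $R$ that truncated narrowband
autocovariances produce (eigenvalues in $[-10^{-10} \lambda_{max}, 0)$ are
clipped; anything more negative is rejected as an invalid autocovariance).
Gamma is never sampled this way: each $\gamma$ realization is assembled
from matching $\theta$ and $x$ realizations, and $y$ by summation.

An independent circulant-embedding sampler (`circulant_draw()`) serves two
purposes: it cross-validates the Toeplitz-root sampler (the two must be
statistically indistinguishable in their lag-domain second moments — a
standing property test), and it generates long paths (e.g. the 20 s paths
used for pulse-duration measurement) in $O(n \log n)$ where the $O(n^3)$
eigendecomposition is impractical. The embedding requires the
autocovariance to have decayed within its supplied lag range; truncating a
still-correlated sequence makes the embedding indefinite and raises an
error, while the benign $\sim 10^{-5}$-relative negative eigenvalues left
by tail truncation are clipped.

Reproducibility: one base seed derives per-realization substream seeds
(recorded in each path's metadata), so ensembles are reproducible as a
whole and per member.

## Spectral estimation

The estimator is deliberately plain: one Hann-tapered periodogram per
realization (unit-energy taper, demeaned path), averaged across the
ensemble. Power estimates the two-sided density in the same convention as
the theoretical spectra, reported on $[0, f_N]$, and satisfies Parseval
exactly. Variance control comes from ensemble averaging (the default 500
realizations, a desk-scale stand-in for a 5000-realization experiment,
leaves $\approx 4.5\%$ per-bin noise). Band measurements:

* `find_peak()`: argmax over a band, refined by three-point parabolic
  interpolation so results are not quantized to the grid;
* `fit_loglog_slope()`: least-squares slope of $\log_{10}$ power vs
  $\log_{10}$ frequency, exact on a pure power law;
* `harmonic_spacing()`: median spacing of detected harmonic peaks.
  Detection operates on amplitude ($\sqrt{\text{power}}$), because the
  harmonic content of smooth gates decays fast in power, and keeps peaks by
  topographic prominence, which ignores the shoulder wiggles of averaged
  estimates. Stochastic-rhythm spectra must be ensemble-averaged first.
* `measure_pulse_durations()`: band-pass via the analytic signal, envelope
  smoothing by a moving average of width $1/(2 \times \text{bandwidth})$,
  pulse segmentation at half the per-cycle local maximum. With a 40 Hz-wide
  latent band the pulsatile gamma pulses last about $1/40\,\mathrm{s} =
  25$ ms, and doubling the bandwidth halves the duration.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| $\Delta$ | 0.001 | s | 1 kHz sampling comfortably contains the 140 Hz band ($f_N = 500$ Hz) |
| $n$ | 1000 | samples | 1 s paths; six theta cycles |
| theta center, width | 6, 2 | Hz | the canonical slow-rhythm peak; 15 Hz is the standard variant |
| x band | 100–140 | Hz | high-gamma; 30–50 Hz low-gamma also supported |
| x edge width | 4 | Hz | cosine rolloff avoids ringing in $r^{(x)}$ |
| $\alpha$, floor | 2, 0.5 | –, Hz | brown-noise background; floor keeps $r_0$ finite |
| $\tau$ | 0 | samples | coupling at the theta peak (no lag stated by the source model) |
| ensemble | 500 | paths | desk-scale; tolerances widened $\sqrt{10}$ vs a 5000-path run |
| n_grid | 8192 | points | lag budget $n_{grid}/2$ covers every acv used at its decay scale |

Component amplitudes are genuinely free parameters of the model (no
published values exist): the defaults set the background an order of
magnitude below the theta peak at $f_\theta$
($S_\eta(f_\theta) = S_\theta(f_\theta)/10$) and give gamma a tenth of
theta's variance ($r^{(\gamma)}_0 = 0.1\, r^{(\theta)}_0$), which makes the
three canonical spectral features — theta peak, $1/f$ background, gamma
bump — simultaneously visible. Both are overridable
(`eta_variance`, `x_variance`).

The gate weights are treated as given constants; they produce the intended
pulse shape only at a definite theta scale, so polynomial gates are applied
to theta normalized to unit variance (the normalization variance is the
path's theoretical variance when known, else its sample variance, and can
be passed explicitly).

The printed preferred-phase formula $\phi_p = \tau / (2 \pi f_\theta)$ is
dimensionally a time, not a radian phase; `preferred_phase()` therefore
reports it verbatim (`printed`) alongside the conventional radian phase
$2 \pi f_\theta \tau \Delta$ (`conventional_rad`) without guessing intent.

## What the generator emulates — and what a green test does not establish

The synthetic world is exactly the stated model: Gaussian, weak-sense
stationary, with coupling injected through a memoryless gate. Real
recordings are none of these things exactly — they show stimulus
transients, drifting rhythm frequency, non-Gaussian spiking contamination
and nonstationary coupling depth. A green suite establishes that the
implementation realizes the stated stochastic processes and their exact
second-order theory; it says nothing about how well that family fits any
particular recording, and fitting is deliberately out of scope.

## Numerical choices

* Frequency grid: odd point count so the grid is exactly symmetric with
  $f = 0$ and both endpoints present; trapezoid endpoint half-weights make
  the quadrature the exact periodic (rectangle) rule, so Wiener–Khintchine
  round trips hold to machine precision for lags below the grid's lag
  budget.
* `acv_to_spectrum()` clips negative ripple; ripple beyond $10^{-3}$
  relative warns (hard-truncated non-decayed sequences, e.g. a pure cosine,
  genuinely have negative Dirichlet sidelobes).
* Eigenvalue clipping: `covariance_sqrt()` at $10^{-10}$ relative (strict:
  full-rank information is available), `circulant_draw()` at $10^{-4}$
  relative (looser: tail truncation of decayed sequences is routine and
  bias-free at this level).
* Degenerate inputs: zero-variance components are allowed and propagate to
  exactly-zero paths; constant paths yield flagged all-zero periodograms;
  out-of-range lagged gate samples are marked invalid (`NA`) rather than
  wrapped or zero-padded, and the model trims all components to the common
  valid window.

## Known limitations

* The pulsatile-model spectrum of $y$ has a gamma bump that is *symmetric
  about 120 Hz but flat to < 0.2 %* across 100–140 Hz under the default
  amplitudes; the measured argmax of a 500-average estimate therefore
  wanders the plateau by up to roughly $\pm 10$ Hz around 120 Hz. The
  bump's *center* is a well-conditioned quantity; its *argmax* is not.
* Ensemble validation of the biphasic gate's second moments at desk scale
  is statistically fraught: the gate reaches $z^8$, so its second moment
  contains $E\{z^{16}\} = 15!! \approx 2 \times 10^6$, an expectation whose
  path-ensemble estimator (and that estimator's own SE) is badly biased low
  at 500 realizations. The test suite validates the biphasic theory by
  direct high-$N$ sampling of correlated theta pairs instead, where the
  tail is actually sampled.
* Long-memory components interact with lag truncation: checks that pass
  through truncated autocovariance products (e.g. the convolution duality)
  need every factor pair to be lag-summable within the grid's lag budget;
  the $1/f^2$ background alone is not, on multi-second scales.
* Nonstationary extensions (drifting coupling, transients) and estimation
  of coupling from data are out of scope.
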