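Package: cfcsim
Title: Stationary Time-Series Models of Phase-Amplitude Cross-Frequency Coupling
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs weak-sense stationary (WSS) Gaussian time-series models
    of phase-amplitude cross-frequency coupling between a slow rhythm (theta)
    and a fast rhythm (gamma) riding on a 1/f^alpha background. Component
    processes are specified by their power spectral densities; autocovariances
    follow from the discrete-time Wiener-Khintchine relation. The gamma
    component is built by gating a latent band-limited process with a
    sinusoidal, pulsatile, or biphasic function of theta. Exact Gaussian
    sample paths are generated with a Toeplitz covariance square-root sampler
    (and an independent circulant-embedding sampler), theoretical second
    moments are obtained in closed form via the Isserlis (Wick) theorem, and
    ensemble-averaged tapered periodograms provide the spectral estimates used
    to compare coupling variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    jsonlite,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
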