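Package: dcsflow
Title: Diffuse Correlation Spectroscopy Processing: Multi-Tau Correlation and Blood Flow Index Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete software processing chain for continuous-wave diffuse
    correlation spectroscopy (DCS): binning of photon arrival events into
    uniform time bins, multi-tau estimation of the normalized intensity
    autocorrelation g2 over a quasi-logarithmic lag schedule, and Nelder-Mead
    fitting of the semi-infinite solution of the correlation diffusion
    equation to extract the blood flow index (BFI, alpha*Db) and coherence
    factor beta. Includes a synthetic speckle photon-stream simulator
    (circulant-embedding complex Gaussian fields, Poisson photon sampling,
    constant, cuff-occlusion and pulsatile flow profiles), a windowed
    counts-to-BFI pipeline with curve validity gating, moving-average
    smoothing and pulsatile spectral analysis, plain-text file formats for
    every intermediate, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    zoo,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
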