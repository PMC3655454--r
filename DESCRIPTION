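Package: caar
Title: Coercively Adjusted Autoregression for Nonlinear, Nonperiodic Time Series
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forecasting tools for nonlinear, nonperiodic biomedical time
    series such as epilepsy EEG. Implements the coercively adjusted
    autoregression (CA-AR) forecaster, an AR model whose coefficients are
    coerced to +1/-1 and re-selected at every forecast origin by an
    exhaustive least-squares sign search, together with box-counting
    fractal-dimension estimation of a signal's planar graph and of its
    delay-coordinate phase space for model-order selection, cepstrum and
    lag-plot diagnostics for periodicity and randomness, synthetic signal
    generators (AR processes, sinusoids, random walks, Weierstrass fractal
    curves, random-coefficient processes), and a rolling one-step forecast
    evaluation harness with standard-AR and nearest-neighbour baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
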