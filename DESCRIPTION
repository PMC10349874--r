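Package: csdea
Title: Complexity Synchronization Analysis of Multichannel Physiological
    Signals via Modified Diffusion Entropy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates time-resolved temporal-complexity scaling indices of
    continuous biosignals (EEG, ECG, respiration) with modified diffusion
    entropy analysis (MDEA): signals are normalized to [0,1], discretized
    into equal-width stripes, stripe crossings define crucial events, and
    the scaling index delta is read off as the slope of the Shannon entropy
    of event-anchored diffusion displacements against the logarithm of the
    window size. Provides sliding-window delta(t) extraction, conversions
    among the complexity indices delta, mu, beta and the fractal dimension
    D, lagged cross-correlation of delta(t) series across channels with
    Fisher confidence intervals (complexity synchronization), signal
    conditioning (zero-phase FIR filtering, average re-referencing,
    decimation), CSV/EDF readers, and generators of renewal crucial-event
    processes with known power-law waiting-time exponents for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
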