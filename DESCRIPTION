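Package: tailhrv
Title: Ultra-Short-Term Heart Rate Variability from Tail-Cuff Plethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis tools for ultra-short-term frequency-domain
    heart rate variability (HRV) in mice. Provides a McSharry-style RR tachogram
    simulator with a bimodal (LF/HF) Gaussian target spectrum and species
    frequency scaling, synthetic volume-pressure-recording pulse waveforms,
    beat detection with sub-sample peak interpolation, a Lomb-Scargle
    periodogram for unevenly sampled interval series with band-power
    extraction over 0.1-1.9 Hz bandings, a Monte-Carlo record-length
    convergence study, and two-group MANOVA (Wilks' lambda) with per-band
    univariate follow-ups, all-pairs cell-mean contrasts and
    Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
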