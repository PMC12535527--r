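Package: triadsync
Title: Heart-Rate-Variability Synchrony in Human-Horse Therapy Triads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for quantifying heart-rate-variability (HRV)
    synchronization between members of a therapy triad (participant,
    riding therapist, therapy horse). Provides RR-interval cleaning
    (duplicate removal, relative-threshold outlier detection, gap
    interpolation, an iterative equine artifact pass), Morlet
    continuous and cross-wavelet transforms with red-noise pointwise
    significance, band-wise extraction of z-scored 10-second
    cross-wavelet power during a stationary "lying" segment, and a
    hierarchical mixed-model ladder (via 'lme4') for testing dyadic
    synchrony transfer and early-life-adversity predictors. A
    synthetic triad generator built on integral pulse frequency
    modulation provides ground-truth coupled RR series for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
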