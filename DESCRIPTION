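Package: ssvepds
Title: Dynamic Reference-Electrode Selection for SSVEP Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for steady-state visual evoked potential (SSVEP)
    frequency detection in multichannel EEG using a dynamically selected
    reference electrode. Implements the all-electrode sum relative-power
    statistic from zero-padded FFT spectra, an exhaustive per-frequency
    scan for the reference electrode maximizing it, threshold calibration
    at a fixed specificity on spontaneous EEG, harmonic-based detection
    rules, a single-source forward simulator of evoked multichannel EEG,
    and a closed-form Monte-Carlo experiment on reference-dependent sum
    power of a sinusoidal field. Includes readers and writers for basic
    16-bit European Data Format (EDF) and a delimited text matrix format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
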