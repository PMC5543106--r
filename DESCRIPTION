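Package: ftirq
Title: Chemometric Calibration of Flavonoid Content from ATR-FT-IR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partial least squares (PLS1) calibration of rutin, quercetin and
    quercitrin concentrations (and their sum) in buckwheat plant material from
    attenuated-total-reflectance Fourier-transform infrared spectra. Provides
    spectral pretreatment chains (first derivative, standard normal variate,
    single-level Haar wavelet approximation and detail coefficients), three
    variable-selection schemes that reduce the spectral variables to one
    quarter before regression (correlation ranking, band-region restriction
    plus correlation, and pure-standard-driven selection), leave-one-out
    selection of the number of latent factors, and a factorial model search
    over 6912 pipeline configurations with SD-based acceptance rules against
    reference HPLC variability. Includes a synthetic ATR-FT-IR data generator
    (Beer-Lambert mixtures of flavonoid standards in a plant matrix) so the
    whole pipeline is testable without instrument data, plus CSV and JCAMP-DX
    spectrum readers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
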