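Package: cystir
Title: ATR-FTIR Quantitation of Insoluble Urinary Cystine, Urea and Creatinine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometrics toolkit for attenuated total reflection Fourier
    transform infrared (ATR-FTIR) quantitation of insoluble urinary cystine
    and of urinary urea and creatinine. Provides spectrum input/output
    (two-column CSV and JCAMP-DX), fractional subtraction of water-vapour and
    liquid-water reference spectra, Savitzky-Golay second-derivative band
    quantitation at 1296 minus 1280 cm-1, through-origin Beer-Lambert
    calibration with a 3-sigma limit of detection, constrained least-squares
    deconvolution of the 1510-1445 cm-1 urea/creatinine region, Bland-Altman
    and Pearson method-comparison statistics, and a forward simulator of
    dried-film and undried-urine spectra with noisy clinical comparator
    measurements so the whole pipeline can be exercised end to end without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
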