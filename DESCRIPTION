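Package: mirqc
Title: Quality Control for Mid-Infrared Spectra of Organic Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the quality of mid-infrared (FTIR) spectra of
    organic matter such as peat. Implements rubberband (convex hull) baseline
    correction, derivation of approximately pure water-vapor and carbon dioxide
    reference spectra from pairs of instrument background scans, quantitative
    indicators for atmospheric water-vapor and CO2 artifacts (relative
    contributions with standard errors, estimated by ordinary least squares
    against the reference spectra), detection of spectra that were already
    baseline corrected, a relative noise level based on Savitzky-Golay
    smoothing residuals, and spectral humification indices. A synthetic
    spectrum generator with known ground truth supports validation of every
    indicator, and command-line entry points wrap the main workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
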