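Package: evlipid
Title: Lipid Composition Analysis for Plasma Extracellular Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Complementary lipidomics toolkit for plasma-derived
    exosome-like vesicles. Builds a phospholipid/sphingolipid mass
    library with predicted fragment ions, assigns MS2 spectra with a
    hypergeometric match score, quantifies assigned species by MS1
    extracted-ion-chromatogram reconstruction with within-headgroup
    relative abundances, processes 31P NMR free-induction decays
    (apodization, Fourier transform, baseline correction, chemical-shift
    calibration, Lorentzian deconvolution) into phospholipid class
    percentages, and computes transwell blood-brain-barrier permeability
    partitions and dynamic-light-scattering summary statistics. A
    synthetic-data generator with known ground truth emulates every
    input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
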