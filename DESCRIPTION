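Package: spectramir
Title: Simulation, Detection, Classification and Calibrated Counting of
    Spectrally Barcoded Single Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for multiplexed single-molecule quantification of
    spectrally barcoded probes imaged through a dispersive (prism-based)
    spectral microscope. Dual-fluorophore reporter probes produce dual-spot
    point-spread functions whose interspot distance encodes target identity.
    The package simulates dispersed spectral PSFs from fluorophore spectra, a
    multiband filter and a wavelength-to-pixel dispersion calibration curve;
    generates synthetic multi-field-of-view image stacks with known ground
    truth; detects and crops candidate molecules; classifies crops with a
    PCA plus RBF-SVM model; and recovers calibrated mixture compositions with
    confusion-matrix count correction and multinomial-resampling uncertainty
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
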