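Package: ptoctr
Title: Photothermal Optical Coherence Tomography Signal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of phase-sensitive photothermal optical
    coherence tomography (PT-OCT) M-scans: spectral-domain OCT reconstruction
    (wavelength-to-wavenumber resampling, dispersion compensation, Chirp-Z
    depth transform), Fourier lock-in extraction of the photothermal phase
    oscillation at the modulation frequency with noise-floor subtraction,
    conversion to nanometers of optical path length, axial motion correction
    against a reference volume, retinal-layer and lesion region-of-interest
    quantification (axial profiles, full width at half maximum,
    peak-to-background), and the study-level statistics (exact two-tailed
    Mann-Whitney U tests and through-origin linear regression). Includes a
    forward simulator producing raw spectral interferograms with known
    photothermal ground truth for pigmented/albino retina phantoms and
    nanorod-labelled lesion phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    grDevices,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png,
    withr
Config/testthat/edition: 3
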