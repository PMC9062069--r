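Package: pvocta
Title: Phase-Variance OCT Angiography Processing for Megahertz Swept-Source Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for swept-source optical coherence tomography
    angiography (OCTA) at multi-megahertz A-scan rates: scan-protocol planning
    (acquisition time, data size, spatial sampling ratios), spectral
    reconstruction of raw interferograms (wavenumber linearization from a
    calibration fringe, fixed-pattern removal, numerical dispersion
    compensation, spectral shaping, zero-padded Fourier reconstruction),
    phase-variance flow contrast with shifted-histogram bulk-motion phase
    correction, retinal pigment epithelium segmentation with Zernike-fit
    flattening, and depth-windowed en face vascular projections. Includes a
    physics-based layered-phantom interferogram simulator with vessel phase
    decorrelation, bulk axial motion, saccades, wavenumber-sampling
    nonlinearity and injected dispersion, so the full pipeline is testable
    without instrument hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
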