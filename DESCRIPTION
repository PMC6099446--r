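Package: lungaerate
Title: Quantitative Lung Aeration from Thoracic MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies lung aeration from conventional magnitude MRI, where
    voxel intensities are uncalibrated grey units. Signal is normalized to a
    reference tissue (water or muscle), calibrated against gravimetric lung
    density on ex vivo lung samples scanned at several airway pressures, and
    the fitted attenuation-versus-gas-fraction line yields intensity
    thresholds separating non-aerated, poorly aerated and normally aerated
    tissue. Thresholds are translated to in vivo thorax scans via an
    atelectasis reference and applied voxel-wise to produce aeration
    compartment reports. Includes mixed-effects calibration with AICc model
    selection, cluster-bootstrap threshold confidence intervals, digital
    phantom generators with Rician noise for validation, and NIfTI/DICOM
    image input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    nlme,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
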