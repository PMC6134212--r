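Package: plsbeam
Title: Partial Least Squares Aided Minimum-Variance Beamforming for MEG
    Source Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes focal neural sources from magnetoencephalography (MEG)
    sensor arrays with a linearly constrained minimum variance (LCMV)
    beamformer, optionally denoised by supervised partial least squares (PLS):
    sensors are grouped into eight anatomical regions, NIPALS PLS extracts
    intrinsic components of the channel-by-time matrix against the region
    class matrix, and the beamformer scans a volumetric grid of the
    reconstructed data for the variance maximum.  Includes an analytic
    conducting-sphere forward model with planar-gradiometer responses, a
    helmet-array and source-grid builder, a sinc-dipole simulator with a
    calibrated Gaussian noise ladder, and an evaluation harness for
    location-error sweeps comparing plain LCMV with the PLS-aided variant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
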