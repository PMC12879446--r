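Package: woifc
Title: Functional Connectivity from Wide-Field Optical Imaging of the Avian Brain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of resting-state functional connectivity from
    wide-field optical intrinsic signal imaging of the dorsal avian brain.
    Converts multi-wavelength reflectance stacks into oxy-/deoxy-hemoglobin
    concentration contrasts via the modified Beer-Lambert law, preprocesses
    them (downsampling, masking, second-order detrending, log-mean transform,
    masked Gaussian smoothing, hemispheric signal regression, zero-phase
    band-pass filtering, time-point censoring), partitions brain pixels with
    SVD-seeded iterative parcellation and hierarchical cluster cutting,
    builds parcel/cluster/region correlation matrices with hemisphere-aware
    reordering and homotopic pairing, and tests connectome consistency with
    matrix-shuffling randomization tests, split-half stability, and the
    Wilcoxon rank-sum contrast of homotopic versus non-homotopic
    correlations. Includes a calibrated synthetic-data generator with known
    region layouts and latent correlation structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    signal,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
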