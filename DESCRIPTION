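Package: voxdose
Title: Voxel-Level Internal Dosimetry with Monte Carlo, Kernel Convolution
    and Convolutional Network Dose Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for voxel-level internal radiation dosimetry of
    positron-emitting radionuclides (default Ga-68) on co-registered
    PET-like activity and CT-like attenuation volumes.  Provides a
    synthetic phantom generator with dynamic time-activity behaviour, a
    simplified voxel Monte Carlo photon/positron dose engine used as the
    ground-truth oracle, voxel S-value (VSV) kernel generation and
    convolution dosimetry, an overlapping-patch extraction and reassembly
    pipeline, a from-scratch 3D U-net regressor mapping PET+CT patches to
    dose-rate patches, and absorbed-dose integration with organ-level
    reporting and paired significance testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
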