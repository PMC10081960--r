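Package: mrfkz
Title: Graph-Convolutional k-Space Interpolation for Stack-of-Spirals 3D
    Magnetic Resonance Fingerprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Accelerates stack-of-spirals 3D magnetic resonance
    fingerprinting (MRF) along the partition-encoding (kz) direction by
    interpolating skipped k-space partitions. Implements self-calibrated
    interpolators trained on auto-calibration (ACS) partitions: spiral
    GRAPPA with location-specific least-squares kernels, a Cartesian 1-D
    convolutional network, and a graph convolutional network whose
    adjacency encodes the non-uniform geometry of the spiral readout.
    Includes an end-to-end synthetic pipeline: digital brain phantom,
    coil sensitivities, fingerprint simulation, spiral k-space sampling
    via a Kaiser-Bessel gridding NUFFT, retrospective undersampling,
    image reconstruction, dictionary template matching for T1/T2/proton
    density, and evaluation metrics (NMSE, relative L1, PSNR, SSIM).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    jsonlite,
    RNifti
Suggests: testthat (>= 3.0.0), yaml, withr
Config/testthat/edition: 3
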