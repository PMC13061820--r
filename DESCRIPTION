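Package: sononet
Title: Spatio-Temporal SonoNet Architectures for Ultrasound Video
    Scan-Plane Classification
Version: 0.1.0
Authors@R:
    person("sononet", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Builds and trains the SonoNet family of convolutional
    networks for ultrasound standard-plane classification: the 2D
    baseline (base widths 16/32/64), a 3D lift that consumes clips of
    consecutive frames, and (2+1)D variants that factorize each 3D
    convolution into a spatial and a temporal convolution (plain,
    parameter-matched "*", and no-intermediate-BN forms).  Includes a
    declarative layer-specification representation with closed-form and
    enumerated parameter/MAC auditing, a clip-based video data pipeline
    (non-overlapping fixed-length clips, matched central-frame 2D
    dataset, patient-disjoint splits, inverse-frequency weighted
    sampling, per-clip augmentation), a seeded synthetic speckled
    ultrasound-video generator with protocolized exams, a CPU training
    loop (Adam, weight decay, early stopping, reduce-on-plateau), and
    clip/video-level evaluation with scan-prior logit masking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
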