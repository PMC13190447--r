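Package: headkin
Title: Validation of Monocular Head-Pose Estimates Against Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for validating video-based head-orientation estimates
    against marker-based motion capture in sports biomechanics. Provides
    exact rotation-group (SO(3)) primitives; construction of reference
    head orientations from a Frankfort-plane marker set with zero-lag
    Butterworth filtering and residual-analysis cutoff selection;
    Karcher-mean estimation and removal of constant anatomical-axis
    offsets; tangent-space Gaussian smoothing of orientation sequences;
    geodesic and incremental geodesic error metrics; occlusion-aware
    detection and face-visibility measures; a nonparametric
    method-comparison battery; and a fully seeded synthetic heading-trial
    generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
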