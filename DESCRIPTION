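Package: dualTrace
Title: Dual-Channel Lineage Tracing with Drift and Rotation Correction for
    Volumetric Embryo Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated lineage tracing of pre-implantation embryos imaged as
    multi-channel 3D time-lapse volumes, where every nucleus carries a global
    green label and a sparse photoconverted population carries an additional
    red label. Provides permissive multiscale Laplacian-of-Gaussian nucleus
    detection, validation filters (embryo-radius outlier removal, double-spot
    merging, red/green colocalization, temporal recovery), rigid drift and
    rotation correction from green/red centers of mass with an exhaustive
    one-degree roll search, two-channel frame-to-frame tracking with division
    detection, condensed lineage-tree comparison via the Zhang-Shasha ordered
    tree edit distance, and a synthetic embryo simulator with full ground
    truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
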