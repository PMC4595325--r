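Package: flow4d
Title: Atlas-Based Segmentation and Flow Quantification for 4D Flow Cardiovascular MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic analysis of time-resolved three-directional
    phase-contrast cardiovascular magnetic resonance data (4D flow CMR).
    Computes phase-contrast MR angiograms, segments the great thoracic
    vessels over the full cardiac cycle by deforming a labelled atlas with
    affine and Morphon-style multi-scale non-rigid registration using
    diffeomorphic field accumulation, places 2D analysis planes by
    principal-component plane fitting, and quantifies net flow volumes by
    integrating through-plane velocities. Includes a pulsatile flow phantom
    generator with analytic ground truth for end-to-end validation, plus
    velocity preprocessing (temporal phase unwrapping and weighted
    second-order polynomial background correction on static tissue).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
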