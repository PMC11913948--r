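Package: wt1map
Title: Water-Selective T1 Mapping with a Continuous Look-Locker Spiral
    Acquisition Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and quantification pipeline for whole-organ
    water-selective T1 (wT1) mapping at 3 Tesla. Implements an Extended
    Phase Graph model of a continuous inversion-recovery Look-Locker
    spiral gradient-echo sequence with slice-profile modeling, dictionary
    generation and complex dictionary matching, two-echo multi-peak
    water-fat separation with a known B0 map, spiral trajectory
    generation with an off-resonance forward model, gridding
    reconstruction and frequency-segmented B0 deblurring, a digital vial
    phantom generator for end-to-end validation without scanner data, and
    ROI/regression analysis utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    rlang,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
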