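Package: nucleophys
Title: Nucleolar Physicochemistry from Refractive-Index Tomograms and
    Fluorescence Correlation Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the physicochemical state of nucleoli in live cells
    from two complementary label-free and fluorescence measurements.
    Provides refractive-index (RI) band segmentation of 3D optical
    diffraction tomograms with connected-component nucleolus detection,
    band-median and voxel-mean RI estimators, voxel volume quantification,
    and time-lapse percent-change summaries; and a fluorescence correlation
    spectroscopy (FCS) arm with Brownian-dynamics trace simulation through a
    3D Gaussian detection volume, direct and multi-tau autocorrelators,
    one- and two-component diffusion model fitting with optional triplet
    correction, rhodamine-6G-referenced diffusion-coefficient calibration,
    and slow-component selection for nucleolar measurements. Synthetic
    phantom and trace generators with ground truth make every analysis step
    testable without instrument data. Condition-comparison statistics
    (group summaries, Student's t-tests, percent-change reports) complete
    the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    tibble,
    dplyr,
    rlang,
    tiff,
    jsonlite,
    yaml,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
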