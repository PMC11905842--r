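Package: exvivomorph
Title: Postmortem Hemisphere MRI Morphometry with Dual-Modality Deep
    Brain Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for morphometry of formalin-immersed postmortem brain
    hemispheres imaged with paired T1- and T2-weighted MRI. Implements
    patch-based convolutional autoencoder brain extraction with logit-sum
    fusion over three slice orientations, normalized-convolution intensity
    correction, restricted-atlas preparation, tissue-constrained multi-atlas
    majority voting, L1 Voronoi tessellation of cerebrum white matter,
    regional white-matter-hyperintensity accounting with corrective volume
    swaps, and robust (Huber) morphometry and neuropathology models.
    Includes a synthetic phantom generator (two-modality hemisphere-in-
    formalin volumes, pseudo-atlases with controlled registration error,
    simulated donor cohorts) providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    RNifti,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
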