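Package: gazestab
Title: Vestibulo-Ocular Performance, Swim Kinematics and Semicircular-Canal
    Morphometry in Larval Amphibians
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit linking semicircular-canal morphology to
    gaze-stabilizing performance and swimming behaviour in larval amphibians
    (Xenopus laevis tadpoles and axolotl). Estimates gain and phase of the
    vestibulo-ocular and optokinetic reflexes from sinusoidal stimulus/eye
    traces via cycle averaging with circular statistics; detects swim bouts
    from pose-tracked landmark trajectories and summarises time-weighted bout
    statistics and head angular-acceleration distributions; quantifies
    spino-ocular (efference-copy) coupling from paired eye-tail traces;
    measures 2D and 3D canal morphometry (circuit and lumen radii, ellipsoid
    elongation and flatness, duct centerline, cross-section profile, stenosis)
    from voxel volumes, including the endolymph-displacement sensitivity model
    X_max = Cst * R * r^2; and integrates per-animal morpho-behavioural
    feature vectors by resampling PCA across cohorts with missing measures.
    Seeded synthetic generators for every input type provide ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++11
Config/testthat/edition: 3
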