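Package: fractometry
Title: Single-Cell Biophysical Fractometry from Quantitative Phase Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the complex optical field of single cells from
    knife-edge phase-gradient images, propagates it to the far field by
    Fourier-transform light scattering, derives angular light-scattering
    profiles and density-correlation curves, estimates fractal dimension
    with fractal-window detection, and assembles a 17-feature fractal/ALS
    profile per cell plus bulk dry-mass morphology. Includes synthetic
    phantom generators (homogeneous spheres with a Mie-series oracle,
    power-law fractal fields, knife-edge forward model, labelled cohorts)
    and the cohort statistics used in morphological profiling: z-scoring,
    Cliff's delta effect sizes, one-versus-all AUROC, linear regression
    classifiers, Spearman correlation networks and feature ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tidyselect,
    tiff,
    utils
Suggests:
    optparse,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
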