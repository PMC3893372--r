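Package: fcdmap
Title: Cortical Thickness Mapping and Morphometry for Focal Cortical Dysplasia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects circumscribed cortical thinning in traced 2D histological
    sections and characterizes the flagged tissue by neuronal morphometry.
    Cortical thickness is measured by solving Laplace's equation between the
    pial and grey/white contours and integrating field lines through the
    grey matter; thickness and curvature are sampled on the mid-cortical
    equipotential. Case sections are screened against matched control
    sections with medcouple-adjusted (skewness-robust) boxplot fences, and
    sub-fence runs are flagged as candidate dysplasias. Segmented neuron
    masks are summarized with Boolean germ-grain model estimates (germ
    intensity, mean grain area and perimeter) and morphological granulometry
    pattern spectra, per cortical lamina. Includes neuron segmentation
    (generalized Gauss-Markov random field relaxation, marker-controlled
    watershed, per-object threshold refinement), Gwet's AC1 inter-rater
    agreement, stereotaxic slide matching, and a synthetic phantom module
    with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
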