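Package: chalign
Title: Searchlight Connectivity Hyperalignment for Individualized
    Functional Topography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts individualized category-selective cortical
    topographies from responses to naturalistic stimuli using searchlight
    connectivity hyperalignment (CHA). Fits per-searchlight orthogonal
    Procrustes transforms between subjects' fine-grained functional
    connectomes on a spherical icosahedral cortical mesh, aggregates them
    into sparse vertex-space transformation matrices, and refines them with
    a coarse-to-fine iterative schedule. Includes the time-locked response
    hyperalignment (RHA) baseline, block-design GLM t-contrast mapping,
    contrast-map prediction from other subjects' localizer data, a
    reliability and correlation evaluation suite (whole-map and searchlight
    Pearson correlations, Cronbach's alpha, fine-connectome similarity,
    Fisher-z comparisons), a synthetic multi-subject cohort generator with
    planted ground-truth misalignments, GIFTI interoperability, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    rlang,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
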