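Package: morphosurf
Title: Parametric 3D Surface Models and Jacobian Morphospaces for Whole-Organism Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for theoretical morphology of whole 3D surfaces. Constructs
    torus-derived parametric surface models of mollusk shells (coiled
    gastropods, turritellids, Vermicularia, limpets, clams, oysters, scallops,
    ammonites, scaphopods), echinoid tests, and basic geometric forms;
    summarizes each surface by the six first partial derivatives of its
    coordinate functions (the Jacobian) evaluated at a reference point;
    post-processes Jacobian-degenerate model pairs with second partial
    derivatives (Hessian elements); computes Darboux frames and principal
    curvatures; reduces measured whorl and aperture radii to actual and
    lowest-integer proportions; and ordinates collections of surfaces in a
    correlation-matrix PCA morphospace, including ontogenetic trajectories.
    Surfaces export as OBJ/PLY point clouds and all summaries as tidy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    grid,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
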