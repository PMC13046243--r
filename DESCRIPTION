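Package: neolaminar
Title: Intracortical Depth Profiling of the Neonatal Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Equivolumetric depth profiling of myelin-sensitive MRI over a
    cortical ribbon: construction of 12 equivolumetric intracortical surfaces
    between matched pial and white meshes, trilinear sampling of a volume at
    each depth, reduction of depth profiles to their central moments (center
    of gravity and variance), parcel-wise linear models of gestational,
    postnatal and postmenstrual age with Benjamini-Hochberg control, geometric
    eigenmodes of the cortical mesh via a linear finite-element
    Laplace-Beltrami operator, and spin-permutation alignment tests between
    effect maps and eigenmodes. Includes a synthetic neonatal-cortex phantom
    with analytically known depth structure so the full pipeline is testable
    end to end without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    xml2,
    RNifti,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
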