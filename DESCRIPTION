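Package: lumbokin
Title: Reduced-Order Biomechanics and Kinematic Verification of the Lumbar Spine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, reduced-order nonlinear model of the human lumbar
    spine (L1 to sacrum). Each motion segment combines an elastic annulus
    foundation, a volumetrically constrained (Mooney-Rivlin or elastic)
    nucleus pulposus with an internal radial-bulge degree of freedom, crossed
    tension-only annulus fibre layers (35 to 80 degrees), bilinear
    tension-only ligaments, and unilateral facet contact. The chain is loaded
    by a 400 N follower preload, external moments and muscle forces; muscle
    force magnitudes are calibrated by minimising the total muscle work
    subject to nonnegativity so that prescribed segmental rotations are
    achieved. Vertebral mobility is measured with endplate reference lines
    and direction cosines, the same procedure applied to synthetic
    radiological cohorts, and the model supports an L5-S1 disc degeneration
    study comparing per-level and global mobility against the healthy spine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
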