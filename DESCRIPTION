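Package: scarabwing
Title: Elastic Wing Deformation, Static Bending and Wing-Shape
    Morphometrics for Flapping Beetle Flight
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify elastic wing deformation and wing-shape
    evolution in flapping insects, built around three linked analyses: (i)
    reconstruction of body-relative flapping, deviation and incidence angles
    from 3D landmark trajectories, with signed, wing-length-normalized
    trailing-edge deflections measured against the rigid leading-edge plane
    and their mid-stroke summaries and deflection-force allometry; (ii)
    flexural stiffness estimation from static point-load cantilever bending
    with dorsal/ventral and wing-support contrasts; and (iii) landmark-based
    geometric morphometrics (generalized Procrustes alignment, shape PCA,
    per-landmark variance contributions, thin-plate-spline warps) with
    phylogenetically corrected PCA under a Brownian-motion model. Fully
    seeded synthetic-data generators (flapping-flight recordings, Brownian
    shape radiations on a phylogeny, cantilever bending experiments) provide
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
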