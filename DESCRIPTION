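Package: ringhydro
Title: Tree-Ring Hydraulic Conductance from Tracheid Anatomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models axial water transport through conifer tree rings using
    only cross-sectional tracheid measurements (radial lumen diameter and
    wall thickness along a radial file). Bordered-pit geometry (membrane,
    torus, aperture, margo pores) is derived from lumen diameter by
    isometric scaling, single-pit resistance is assembled from margo,
    canal, and aperture terms, per-tracheid resistance combines the
    Hagen-Poiseuille lumen term with the parallel pit network on the
    radial walls, and ring conductance is the parallel sum over the
    tracheidogram. Includes earlywood/latewood partitioning by Mork's
    rule, pit-contribution diagnostics, cumulative conductance profiles,
    a synthetic tracheidogram generator for sensitivity experiments, and
    delimited-text input/output for cell-anatomy pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
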