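Package: voxelnav
Title: Quantifying 3D Navigation Behaviour on Voxel Terrain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing object-location learning in 3D voxel
    environments. Models walkable terrain as a weighted directed graph with
    asymmetric vertical movement costs and computes shortest-path (Dijkstra)
    distances; segments 1 Hz training trajectories into object-to-object
    segments and derives per-segment cost-difference curves (actual minus
    optimal cost-to-go); clusters the curves by K-means on cubic B-spline
    coefficients with silhouette-based model selection and seed-stability
    diagnostics; and relates training behaviour to spatial-memory test
    outcomes through penalised scalar-on-functional regression with
    bootstrap confidence bands. Includes an agent-based simulator of
    navigation styles so the full pipeline can be exercised and validated
    on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    splines,
    stats,
    graphics,
    utils,
    cluster,
    mclust,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
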