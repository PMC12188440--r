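Package: troopline
Title: Detection and Analysis of Collective Travel Progressions from
    Multi-Individual GPS Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying collective travel ("progressions") in
    group-living animals tracked with simultaneous high-resolution GPS.
    Provides trajectory cleaning and local planar projection, per-second
    group kinematics (polarization, speed, elongation, cohesion),
    automated quantile-threshold detection of progression events,
    projection of individuals into the moving group reference frame,
    proximity-based social networks with eigenvector centrality,
    nearest-neighbour Markov-chain consistency, a linear mixed-model
    battery with repeatability (ICC), and a ground-truthed synthetic
    trajectory generator for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    glmmTMB,
    igraph,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    geosphere,
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
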