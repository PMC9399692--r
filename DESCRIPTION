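Package: myovol
Title: Headless Three-Dimensional Muscle Volume Reconstruction from Bone
    Meshes and Attachment Areas
Version: 0.1.0
Authors@R:
    person("Muscle", "Toolkit", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs watertight three-dimensional muscle volumes from
    triangle-mesh bone surfaces and painted origin/insertion attachment
    areas.  A centerline curve spanning the attachment centroids is built
    and optionally adjusted; the origin boundary cross-section is swept
    along the curve with rotation-minimizing frames and joined to both
    attachments; muscle-bone and muscle-muscle overlap is removed by
    grid-based Boolean differences.  Exports per-muscle metrics (attachment
    areas and centroids, linear and curved lengths, enclosed volume) plus
    frustum-volume, physiological cross-sectional area (PCSA) and muscle
    force comparison statistics.  Includes deterministic analytic fixture
    generators (cylinder, curved channel, overlapping pair) so the whole
    pipeline is testable against closed-form geometry, and a command-line
    interface for batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
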