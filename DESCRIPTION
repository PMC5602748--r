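Package: sdtraj
Title: Reconstruction of Spreading Depolarization Trajectories on Cortical Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs candidate trajectories of the curvature center of a
    spreading depolarization (SD) wave-front on a triangulated cortical
    surface from time-of-SD-arrival-differences (TOADs) recorded by a
    subdural electrode strip, and estimates SD propagation velocity.
    Provides triangle-mesh input/output (OFF, FreeSurfer ASCII, PLY),
    interpolating 4-split up-sampling, edge-length-preserving Laplacian
    smoothing, patch extraction, edge-graph geodesics, electrode
    localization from metal-bright volumes, SD hit-sequence handling with
    branch reduction, a layered dynamic-programming trajectory search with
    exact big-integer solution counting, trajectory heatmaps and sampling,
    TOAD-weighted velocity estimation, leave-one-electrode-out validation,
    and a synthetic-data generator (meshes, electrode strips, simulated
    waves, CT-like volumes) that makes the full pipeline testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
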