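Package: tomofil
Title: Tracing Semiregular Filament Bundles in Cryo-Electron Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects loosely aligned, roughly co-oriented filaments (such as
    actin bundles) in noisy 3D cryo-electron tomography density maps. The
    core is a dynamic-programming path-density filter: forward and backward
    accumulated path densities over a 45-degree bipyramidal search window
    are blended into a contrast-enhanced map, from which short candidate
    filament segments are traced bottom-up from local seed points, screened,
    and fused into full filament traces. Includes a tomogram simulator
    (Gaussian volumization of filament models, colored noise, missing-wedge
    Fourier masking) and a voxel-level precision/recall/F1 validator, so the
    whole pipeline can be benchmarked against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    knitr
Config/testthat/edition: 3
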