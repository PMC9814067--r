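Package: tomoalign
Title: Pre-Acquisition Tomographic Alignment on a Virtual Beamline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage pre-acquisition alignment for (scanning) tomography
    experiments: rotation-axis tilt correction from the elliptical detector
    trajectory of a strongly absorbing fiducial particle, followed by sample
    centering on the rotation axis, each refined by a seeded genetic
    algorithm with evaluation caching. Ships a virtual parallel-beam
    beamline (seeded synthetic phantoms, misalignment motors, Radon-style
    forward projector with per-projection axis jitter) so the whole workflow
    runs end to end without hardware, plus tidy accessors, ggplot2 plots and
    TIFF/CSV/JSON interchange for projections, tracks and reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
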