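Package: voltrackr
Title: Segmentation and Tracking of Cell Nuclei in 3D Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for following individual cell nuclei through volumetric
    (3D + time) fluorescence movies. Cells are detected by a pluggable voxel
    classifier followed by a two-stage (2D then 3D) seeded watershed; identities
    are propagated across time by a learned point-matching network trained on
    simulated deformations, refined by EM-based non-rigid point-set registration
    with a motion-coherence prior, and snapped onto detected cell regions by an
    intensity-guided correction step. Includes single and ensemble tracking
    modes, relative-movement difficulty metrics, degradation experiments
    (noise, temporal subsampling, z binning), ratiometric activity extraction,
    and a synthetic-scene generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
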