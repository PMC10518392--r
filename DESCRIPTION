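Package: pedplan
Title: Pedicle Screw Trajectory Planning and Gertzbein-Robbins Grading on
    Labeled Vertebral Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic geometric engine for preoperative pedicle screw
    planning on segmented computed-tomography volumes. Generates parametric
    vertebra phantoms with exact ground-truth geometry, measures pedicle
    corridors (axis, width, entry region, depth to the anterior cortex, wall
    clearances) from an anatomical label map, enumerates and sizes screw
    trajectories under explicit placement constraints (maximal catalog length
    up to the vertebral front end, diameter capped at 90 percent of the
    pedicle width, >= 1 mm medial and inferior wall margins, no endplate
    violation), ranks trajectories by a bone-density-weighted pullout-force
    proxy, grades arbitrary screw poses on the Gertzbein-Robbins scale by
    breach depth, and provides the paired t and Fisher exact statistics used
    to compare planned and freehand cohorts.
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
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
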