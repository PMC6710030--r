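Package: spinefit
Title: Geometric Congruence of Spinal Surface Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the geometric congruence (self-symmetry) of posterior
    spinal exposure surface point clouds, the property that destabilises
    surface-based image-to-patient registration in navigated spine surgery.
    Fits symmetric primitives (plane, sphere, cylinder) with a seeded RANSAC
    loop, scores congruence with the inliers-to-points ratio (ITPR) and the
    coefficient of variation of the RANSAC RMSE, reconstructs bilateral and
    unilateral exposure groups from labelled clouds, runs cohort-level studies
    with percent-reduction summaries, and provides one-way ANOVA, Tukey HSD
    and Levene tests for ITPR records. Includes a parametric synthetic
    vertebra surface generator so the full pipeline is testable without
    optical scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
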