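Package: aorta4d
Title: Aortic Biomechanics from Time-Resolved 3D Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies thoracic aortic biomechanics from 4D (3D + cardiac phase)
    binary lumen segmentations: medialness-weighted centerline extraction with
    landmark-anchored perpendicular planes, non-rigid surface registration for
    displacement mapping, 3D and motion-corrected 2D distensibility, ascending
    aortic longitudinal strain, and the aortic tortuosity index. Includes a
    deforming-tube phantom generator with fully analytic ground truth, a cohort
    simulator, and a statistics stage (one-way ANOVA with a Bonferroni gate,
    Tukey HSD, univariate-to-multivariate linear regression with variance
    inflation factor screening, and Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    car,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    oro.nifti
Config/testthat/edition: 3
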