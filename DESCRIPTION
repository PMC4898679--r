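Package: foldconn
Title: Coupling of Cortical Gyrification and White-Matter Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Surface-based morphometry and diffusion-tensor tractography for
    studying how local cortical folding relates to the microstructure of the
    white matter beneath it. Implements the local gyrification index on
    triangulated cortical surfaces with an outer-hull construction and
    geodesic-disc patch areas, vertex-wise general linear models with
    random-field-theory cluster correction (validated by a permutation
    oracle), deterministic tensor streamline tractography with
    surface-seeded endpoint dissection, Hartigan dip tests and Gaussian
    mixture modelling of streamline length distributions with cross-validated
    component selection and short/long tract classification, and the
    group-level coupling statistics (per-metric GLMs with Bonferroni control,
    moderation models, seemingly unrelated regressions with cross-equation
    chi-squared tests, and partial correlations). A synthetic-cohort module
    generates folded surfaces, tensor phantoms with planted fiber bundles,
    and two-group covariate tables with known ground truth so the whole
    pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    xml2,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
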