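Package: pgsmap
Title: Spatially Weighted Polygenic Score Association Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps spatial variation in the association between polygenic
    scores and quantitative traits across a study region. Builds weighted
    polygenic scores from genotype dosages and GWAS summary statistics at
    multiple p-value thresholds, estimates the local PGS-trait regression
    coefficient at every node of a hexagonal analysis grid using
    inverse-distance participant weights, and compares the resulting maps
    to each other and to environmental surfaces with Lee's bivariate
    spatial correlation statistic under a Monte-Carlo permutation null.
    Includes a synthetic-cohort generator with a planted spatially varying
    genetic effect so every stage of the pipeline can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    grid,
    Matrix,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
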