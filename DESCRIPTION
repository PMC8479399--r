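Package: gwpca
Title: Geographically Weighted Principal Component Analysis for Spatial
    Multivariate Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterising spatial heterogeneity in georeferenced
    multivariate data such as soil heavy-metal concentration surveys. Provides
    conventional principal component analysis on standardized data with
    proportion-of-total-variance accounting and the eigenvalue-greater-than-one
    retention rule; geographically weighted summary statistics (means, standard
    deviations, covariances, correlations) under bi-square kernel weighting;
    geographically weighted PCA with per-location eigenstructure, local scores,
    cumulative-variance surfaces, winning-variable maps, and leave-one-out
    cross-validated bandwidth selection; a synthetic-data generator with
    planted spatial covariance regimes for method validation; and CSV/GeoJSON
    export of all spatial products.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
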