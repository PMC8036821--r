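Package: greensar
Title: Spatial Regression of Neighborhood Tree and Greenspace Metrics on
    Area-Level Health Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ecological (area-level) analysis of health outcome
    rates against high-resolution tree-canopy and greenspace structure.
    Computes per-tract landscape metrics from binary canopy rasters (cover
    fraction, median patch size, nearest-neighbor index of patch centroids,
    land-use-stratified greenspace fractions), builds row-standardized
    contiguity weights, screens with Moran's I and variance inflation
    factors, and fits spatial lag and spatial error regressions by maximum
    likelihood using the concentrated log-likelihood with an eigenvalue
    log-determinant. A synthetic-landscape generator with a known
    data-generating process makes every stage testable without restricted
    administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
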