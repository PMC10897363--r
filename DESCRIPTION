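Package: urbannature
Title: Quantifying Urban Green and Natural Space Against Urban Nature Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for quantifying urban green and natural
    (green plus blue) space from 10 m landcover and NDVI rasters, evaluating a
    city against the two C40 Urban Nature Declaration targets (Quality Total
    Cover: 30-40% green area; Equitable Spatial Distribution: 70% of the
    population within a 1,000 m walk of at least 0.5 ha of contiguous natural
    space), and converting those area- and access-based targets into
    city-specific NDVI values usable with epidemiological exposure-response
    functions. Includes greenest-pixel NDVI compositing, landcover
    reclassification to binary greenspace masks, contiguous-patch filtering and
    circular-buffer accessibility at native resolution, population-weighted
    exposure summaries, per-city ordinary least squares target conversion, and
    a seeded synthetic-city generator (correlated landcover fields, per-date
    reflectance bands with clouds and seasonality, population and boundary
    layers) so the whole pipeline runs and is testable without satellite
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
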