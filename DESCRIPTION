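Package: uavphenome
Title: Histogram Phenotyping of UAV Vegetation-Index Imagery for Maize Trait Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for plot-level aerial crop phenotyping from
    near-infrared/green/blue (NGB) imagery. Computes the blue-band normalized
    difference vegetation index (BNDVI) per pixel, segments canopy from soil,
    summarises each plot at each flight date as a 999-bin BNDVI histogram,
    decomposes the stacked histogram matrix by principal component analysis
    with eigenvector back-projection sweeps for interpretation, correlates
    component scores with agronomic traits (flowering time, grain yield,
    kernel dimensions) date by date, and predicts traits by partial least
    squares regression with repeated 30% hold-out and factor-threshold
    selection. Includes a synthetic field-season generator that emulates
    canopy closure, a pre-flowering BNDVI dip, senescence and a stay-green
    yield coupling, so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
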