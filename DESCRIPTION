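Package: wheatagb
Title: Winter Wheat Daily Aboveground Biomass by Crop Model Calibration
    and Satellite LAI Assimilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reduced-form WOFOST-style daily winter-wheat growth simulator
    together with the two estimation layers needed to turn sparse agronomic
    statistics into gridded daily aboveground biomass (AGB): zonal
    maximum-likelihood calibration of crop and irrigation parameters against
    county yield statistics and station observations (Thiessen-polygon
    zoning, Mahalanobis log-likelihood over jointly calibrated years, a
    three-step crop/irrigation/crop strategy), and per-pixel variational
    assimilation of 8-day satellite leaf area index through a normalized
    weak-constraint cost minimized over emergence date, leaf life span and
    pre-anthesis thermal time. A synthetic-data module generates weather,
    stations, counties and satellite-like LAI with the statistical structure
    the analysis assumes, so the whole pipeline is testable end to end.
    Harvest-year products are written as 270-band daily rasters in kg/ha.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
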